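test_that("transcript-to-genome hits keep strand bookkeeping straight", {
  set.seed(12)
  mod <- random_seq(120)
  ctg_plus <- contig("p", paste0(random_seq(200), mod, random_seq(200)))
  ctg_minus <- contig("m", paste0(random_seq(150),
                                  reverse_complement(mod), random_seq(150)))
  tr <- c(t1 = mod)
  h <- local_align_transcript(tr, list(p = ctg_plus, m = ctg_minus))
  hp <- h[h$contig_id == "p", ]
  hm <- h[h$contig_id == "m", ]
  expect_equal(nrow(hp), 1L)
  expect_equal(hp$gstart, 200L)
  expect_equal(hp$gend, 320L)
  expect_equal(hp$strand, "+")
  expect_equal(hm$strand, "-")
  expect_equal(extract_interval(ctg_minus,
                                interval("m", hm$gstart, hm$gend, "-")), mod)
})

test_that("modules of a multi-module gene tile the transcript", {
  sim <- simulate_dataset(small_cfg(1))
  tm <- sim$truth$modules
  g <- names(which.max(table(tm$gene)))
  skip_if(sum(tm$gene == g) < 3)
  hits <- local_align_transcript(sim$truth$mature[g], sim$contigs)
  expect_equal(nrow(hits), sum(tm$gene == g))
})

test_that("module boundaries and junctions are recovered exactly", {
  for (s in 1:3) {
    sim <- simulate_dataset(small_cfg(s))
    ann <- annotate_transcripts(sim$truth$mature, sim$contigs)
    tm <- sim$truth$modules
    key <- function(m) paste(m$gene, m$ordinal, m$contig_id, m$start, m$end,
                             m$strand, m$tstart, m$tend)
    expect_equal(sum(key(ann$modules) %in% key(tm)), nrow(tm),
                 info = paste("seed", s))
    tj <- sim$truth$junctions
    kj <- function(j) paste(j$gene, j$after_ordinal, j$tpos, j$tract_len,
                            j$width)
    expect_equal(sum(kj(ann$junctions) %in% kj(tj)), nrow(tj),
                 info = paste("seed", s))
  }
})

test_that("junction ambiguity is resolved upstream-maximal for widths 0-6", {
  set.seed(13)
  for (w in 0:6) {
    ## transcript = A-part + B-part; the genome encodes the first w bases
    ## of B also at the end of A's module copy
    apart <- random_seq(120)
    bpart <- random_seq(130)
    tr <- paste0(apart, bpart)
    shared <- substr(bpart, 1, w)
    stopmark <- if (substr(bpart, w + 1, w + 1) == "A") "C" else "A"
    ctgA <- contig("cA", paste0(random_seq(80), apart, shared, stopmark,
                                random_seq(80)))
    junk <- random_seq(81)
    ## make sure the base right before B's copy breaks the backward run
    pre <- if (substr(apart, 120, 120) == "G") "T" else "G"
    ctgB <- contig("cB", paste0(junk, pre, bpart, random_seq(80)))
    ann <- annotate_transcripts(c(g = tr), list(cA = ctgA, cB = ctgB))
    j <- ann$junctions[!ann$junctions$terminal, ]
    expect_equal(j$tpos, 120L + w, info = paste("width", w))
    expect_equal(j$width, w, info = paste("width", w))
    m <- ann$modules
    expect_equal(m$tend[m$ordinal == 1], 120L + w)
    expect_equal(m$tstart[m$ordinal == 2], 120L + w)
  }
})

test_that("an internal poly-U gap is accepted as a U-appendage locus", {
  set.seed(14)
  apart <- paste0(random_seq(119), "G")   # no genome-encoded terminal T
  bpart <- paste0("G", random_seq(119))
  tr <- paste0(apart, strrep("T", 12), bpart)
  ctgA <- contig("cA", paste0(random_seq(80), apart, "C", random_seq(80)))
  ctgB <- contig("cB", paste0(random_seq(80), "G", bpart, random_seq(80)))
  ann <- annotate_transcripts(c(g = tr), list(cA = ctgA, cB = ctgB))
  j <- ann$junctions[!ann$junctions$terminal, ]
  expect_equal(j$tract_len, 12L)
  expect_equal(j$rule, "downstream-of-T")
})

test_that("a deleted module yields a missing-module diagnostic", {
  sim <- simulate_dataset(small_cfg(2))
  tm <- sim$truth$modules
  g <- names(which.max(table(tm$gene)))
  mid <- tm[tm$gene == g, ]
  mid <- mid[order(mid$ordinal), ][2, ]  # ablate the second module
  ctgs <- sim$contigs
  ctgs[[mid$contig_id]] <- NULL
  ann <- annotate_transcripts(sim$truth$mature[g], ctgs)
  expect_true(!is.null(ann$diagnostics) &&
                any(ann$diagnostics$kind == "missing-module"))
})

test_that("nested modules report frames and amino-acid overlap", {
  sim <- simulate_dataset(small_cfg(6, n_genes = 8L, nesting_events = 1L,
                                    nesting_overlap_bp = 66L))
  ov <- find_module_overlaps(sim$truth$modules)
  nested <- ov[ov$nested & ov$strand_relation == "same", ]
  expect_gte(nrow(nested), 1L)
  expect_true(all(nested$frames_equal))
  expect_true(any(nested$overlap_bp == 66L & nested$overlap_aa == 22L))

  ## opposite-strand overlap carries no amino-acid overlap
  sim2 <- simulate_dataset(small_cfg(6, n_genes = 8L,
                                     opposite_overlap_events = 1L))
  ov2 <- find_module_overlaps(sim2$truth$modules)
  opp <- ov2[ov2$strand_relation == "opposite", ]
  expect_gte(nrow(opp), 1L)
  expect_true(all(is.na(opp$overlap_aa)))

  ## disjoint modules produce no overlap records
  mods <- module_table(gene = c("a", "b"), ordinal = c(1L, 1L),
                       contig_id = c("c", "c"), start = c(0L, 500L),
                       end = c(100L, 600L), strand = c("+", "+"),
                       frame_offset = c(0L, 0L), tstart = c(0L, 0L),
                       tend = c(100L, 100L))
  expect_equal(nrow(find_module_overlaps(mods)), 0L)
})

test_that("same-strand nested pairs in simulator truth are always in frame", {
  for (s in 1:3) {
    sim <- simulate_dataset(small_cfg(s, n_genes = 8L, nesting_events = 1L))
    ov <- find_module_overlaps(sim$truth$modules)
    nested <- ov[ov$nested & ov$strand_relation == "same", ]
    expect_true(all(nested$frames_equal), info = paste("seed", s))
  }
})

test_that("trans-splicing errors are classified with the documented priority", {
  sim <- simulate_dataset(small_cfg(3, splice_error_rates = c(0, 0, 0, 0)))
  want <- sim$truth$mature
  jm <- sim$truth$junctions[!sim$truth$junctions$terminal, ]
  g1 <- names(want)[1]; g2 <- names(want)[2]
  j1 <- jm[jm$gene == g1, ][1, ]
  ## exact fragment -> none
  frag <- substr(want[[g1]], max(1, j1$tpos - 150), j1$tpos + 150)
  expect_equal(classify_junction_errors(frag, want, jm), "none")
  ## type iv: joins modules of two genes
  f4 <- paste0(substr(want[[g1]], max(1, j1$tpos - 150), j1$tpos),
               substr(want[[g2]], 1, 150))
  expect_equal(classify_junction_errors(f4, want, jm), "iv")
  ## type ii: extra Us at a junction without a tract
  plain <- jm[jm$tract_len == 0L, ][1, ]
  tr <- want[[plain$gene]]
  f2 <- paste0(substr(tr, max(1, plain$tpos - 150), plain$tpos), "TT",
               substr(tr, plain$tpos + 1, min(nchar(tr), plain$tpos + 150)))
  expect_equal(classify_junction_errors(f2, want, jm), "ii")
  ## type i: small deletion at a plain junction
  f1 <- paste0(substr(tr, max(1, plain$tpos - 150), plain$tpos - 2),
               substr(tr, plain$tpos + 1, min(nchar(tr), plain$tpos + 150)))
  expect_equal(classify_junction_errors(f1, want, jm), "i")
  ## type iii: genomic 3' extension instead of the U tract
  withtr <- jm[jm$tract_len >= 3L, ]
  if (nrow(withtr)) {
    jt <- withtr[1, ]
    trq <- want[[jt$gene]]
    mods <- sim$truth$modules
    mi <- which(mods$gene == jt$gene & mods$ordinal == jt$after_ordinal)
    flank <- mitomosaic:::module_context(mods, sim$contigs, mi, "down",
                                         jt$tract_len)
    f3 <- paste0(substr(trq, max(1, jt$tpos - 150), jt$tpos), flank,
                 substr(trq, jt$tpos + jt$tract_len + 1,
                        min(nchar(trq), jt$tpos + jt$tract_len + 150)))
    expect_equal(classify_junction_errors(f3, want, jm), "iii")
  }
})
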