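test_that("RNA/DNA pairing is gapless with only a trailing RNA run", {
  p <- align_rna_dna("ACGTT", "ACGTT")
  expect_true(all(p$dna == p$rna))
  expect_equal(p$trailing_rna, "")
  p2 <- align_rna_dna("ACGTTTT", "ACG")
  expect_equal(p2$trailing_rna, "TTTT")
  ## a frame-shifting internal indel is rejected
  expect_error(align_rna_dna("ACG", "ACGTT"), "indel")
  set.seed(30)
  a <- random_seq(60)
  shifted <- paste0(substr(a, 1, 20), substr(a, 23, 60), "AC")
  expect_error(align_rna_dna(shifted, a), "indel")
})

test_that("substitution calls respect editing directionality and SNP subtraction", {
  p <- align_rna_dna("AGCGA", "AACGA")
  res <- call_substitutions(p)
  expect_equal(res$sites$kind, "A-to-I")
  expect_equal(res$sites$pos, 1L)

  ## DNA C / RNA U at a known SNP position is subtracted, not called
  p2 <- align_rna_dna("ATTGA", "ATCGA")
  res2 <- call_substitutions(p2, snp_table = data.frame(pos = 2L))
  expect_equal(nrow(res2$sites), 0L)
  expect_equal(res2$subtracted, 2L)

  ## DNA G / RNA A is not an editing direction: rejected column
  p3 <- align_rna_dna("AACGA", "AGCGA")
  res3 <- call_substitutions(p3)
  expect_equal(nrow(res3$sites), 0L)
  expect_equal(res3$rejected, 1L)
})

test_that("U-appendage length attributes genome-encoded Ts maximally", {
  expect_equal(call_u_appendage("ACG", "ACGTTTTT"), 5L)
  expect_equal(call_u_appendage("ACGTT", "ACGTTTTT"), 3L)
  expect_equal(call_u_appendage("ACG", "ACGA"), 0L)
  expect_error(call_u_appendage("ACG", "TTTT"), "does not begin")
})

test_that("long simulated tracts are recovered at exact length", {
  sim <- simulate_dataset(small_cfg(31, n_genes = 4L,
    gene_names = c("atp6", "cob", "rns", "y5"), templates = list(
    list(name = "y5", core_lengths = c(120L, 90L), tracts = c(49L, 0L)))))
  tj <- sim$truth$junctions
  y5 <- tj[tj$gene == "y5" & !tj$terminal, ]
  ann <- annotate_transcripts(sim$truth$mature, sim$contigs)
  aj <- ann$junctions[ann$junctions$gene == "y5" & !ann$junctions$terminal, ]
  expect_equal(aj$tract_len, y5$tract_len)
  expect_gte(y5$tract_len, 45L)  # generated 49, minus possible absorption
})

test_that("cluster calling equals the single-linkage oracle", {
  cl <- cluster_sites(data.frame(pos = c(10L, 12L, 15L)))
  expect_equal(nrow(cl), 1L)
  expect_equal(c(cl$span_start, cl$span_end), c(10L, 15L))
  expect_equal(nrow(cluster_sites(data.frame(pos = c(10L, 40L)))), 0L)
  set.seed(32)
  for (i in 1:20) {
    pos <- sort(sample(1:200, sample(2:6, 1)))
    got <- cluster_sites(data.frame(pos = pos), max_gap = 20L, min_sites = 2L)
    want <- cluster_oracle(pos, 20L, 2L)
    expect_equal(nrow(got), length(want))
    if (length(want)) {
      expect_equal(got$span_start, vapply(want, min, 0L))
      expect_equal(got$span_end, vapply(want, max, 0L))
      expect_equal(got$n_sites, lengths(want))
    }
  }
})

test_that("every simulated editing event is recovered with no false calls", {
  for (s in 1:3) {
    sim <- simulate_dataset(small_cfg(s))
    ann <- annotate_transcripts(sim$truth$mature, sim$contigs)
    snps <- data.frame(contig = sim$truth$snps$contig_id,
                       pos = sim$truth$snps$gpos)
    ed <- call_editing(sim$truth$mature, ann$modules, ann$junctions,
                       sim$contigs, snps = snps)
    te <- sim$truth$editing
    ts <- te[te$kind != "U-append", ]
    tu <- te[te$kind == "U-append", ]
    got_s <- paste(ed$sites$gene, ed$sites$kind, ed$sites$pos)
    want_s <- paste(ts$gene, ts$kind, ts$tpos)
    expect_setequal(got_s, want_s)
    got_u <- paste(ed$utracts$gene, ed$utracts$tpos, ed$utracts$length)
    want_u <- paste(tu$gene, tu$tpos, tu$len)
    expect_setequal(got_u, want_u)
    ## genomic-base invariants on every call
    for (i in seq_len(nrow(ed$sites))) {
      g <- ed$sites$gene[i]
      m <- ann$modules[ann$modules$gene == g &
                         ann$modules$tstart <= ed$sites$pos[i] &
                         ann$modules$tend > ed$sites$pos[i], ][1, ]
      gs <- module_seq(m, sim$contigs, 1)
      base <- substr(gs, ed$sites$pos[i] - m$tstart + 1,
                     ed$sites$pos[i] - m$tstart + 1)
      expect_equal(base, if (ed$sites$kind[i] == "A-to-I") "A" else "C")
    }
  }
})

test_that("SNP subtraction removes SNP-caused candidates when the table is given", {
  sim <- simulate_dataset(small_cfg(33, snp_rate = 0.0025))
  skip_if(nrow(sim$truth$snps) == 0)
  ann <- annotate_transcripts(sim$truth$mature, sim$contigs)
  snps <- data.frame(contig = sim$truth$snps$contig_id,
                     pos = sim$truth$snps$gpos)
  with_tab <- call_editing(sim$truth$mature, ann$modules, ann$junctions,
                           sim$contigs, snps = snps)
  no_tab <- call_editing(sim$truth$mature, ann$modules, ann$junctions,
                         sim$contigs, snps = NULL)
  te <- sim$truth$editing
  want_s <- paste(te$gene[te$kind != "U-append"], te$tpos[te$kind != "U-append"])
  false_with <- sum(!(paste(with_tab$sites$gene, with_tab$sites$pos) %in% want_s))
  false_without <- sum(!(paste(no_tab$sites$gene, no_tab$sites$pos) %in% want_s))
  expect_equal(false_with, 0L)
  n_conf <- sum(sim$truth$snps$confusable)
  if (n_conf > 0) expect_gt(false_without, 0L)
})

test_that("U-tract lengths compensate reading frame across species", {
  tab <- data.frame(gene = "nad5", module = 11L,
                    species = c("sp1", "sp2"),
                    module_len = c(100L, 97L), tract_len = c(2L, 5L))
  r <- u_tract_frame_compensation(tab)
  expect_true(all(r$pass))
  tab$module_len[2] <- 98L
  r2 <- u_tract_frame_compensation(tab)
  expect_false(any(r2$pass))
  expect_equal(r2$delta_mod3, 2L)  # (102 - 103) mod 3
  ## a module shortened by 26 with a 26-U tract vs the full module
  tab3 <- data.frame(gene = "nad5", module = 11L,
                     species = c("a", "b"),
                     module_len = c(120L, 94L), tract_len = c(0L, 26L))
  expect_true(all(u_tract_frame_compensation(tab3)$pass))
})

test_that("A+T equalization reports max-minus-min percentage points", {
  g <- c(sp1 = strrep("AT", 30), sp2 = paste0(strrep("AT", 22),
                                              strrep("GC", 28)))
  ## A+T 1.00 vs 0.44 -> 56 points
  r <- at_equalization(g, g)
  expect_equal(r$pre_diff_pct, 56)
  expect_equal(r$post_diff_pct, 56)
  expect_equal(at_equalization(c(a = "ACGT", b = "ACGT"),
                               c(a = "ACGT", b = "ACGT"))$pre_diff_pct, 0)
  expect_error(at_equalization(c(a = "ACGT"), c(a = "ACGT")), "two species")
  expect_error(at_equalization(c(a = "", b = "A"), c(a = "A", b = "A")),
               "empty")
  ## directional editing narrows the spread: A-to-I (A->G) lowers A+T in
  ## the A+T-rich species, C-to-U (C->T) raises it in the poor one
  set.seed(34)
  rich <- paste(sample(c("A", "T", "G", "C"), 600, TRUE,
                       prob = c(.4, .3, .15, .15)), collapse = "")
  poor <- paste(sample(c("A", "T", "G", "C"), 600, TRUE,
                       prob = c(.2, .2, .3, .3)), collapse = "")
  edit_dir <- function(s, from, to, k) {
    v <- strsplit(s, "")[[1]]
    idx <- sample(which(v == from), k)
    v[idx] <- to
    paste(v, collapse = "")
  }
  rich_ed <- edit_dir(rich, "A", "G", 60)   # A-to-I in the A+T-rich genome
  poor_ed <- edit_dir(poor, "C", "T", 60)   # C-to-U in the A+T-poor genome
  r2 <- at_equalization(c(rich = rich, poor = poor),
                        c(rich = rich_ed, poor = poor_ed))
  expect_lt(r2$post_diff_pct, r2$pre_diff_pct)
})
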