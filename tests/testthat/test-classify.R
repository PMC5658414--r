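## constructed contigs: class = shared 150 bp motifs around a unique insert
make_classified_set <- function(seed = 20, n = 3, motif_len = 150,
                                motif_identity = 1) {
  set.seed(seed)
  up <- random_seq(motif_len); down <- random_seq(motif_len)
  ctgs <- list(); mods <- NULL
  for (i in seq_len(n)) {
    mod <- random_seq(120)
    pre <- random_seq(1200); post <- random_seq(1200)
    fl_up <- random_seq(80); fl_dn <- random_seq(80)
    upi <- if (motif_identity < 1)
      mitomosaic:::mutate_seq(up, 1 - motif_identity) else up
    seq <- paste0(pre, upi, fl_up, mod, fl_dn, down, post)
    id <- sprintf("k%02d", i)
    ctgs[[id]] <- contig(id, seq, circular = TRUE)
    s0 <- nchar(pre) + nchar(upi) + 80L
    mods <- rbind(mods, data.frame(
      gene = paste0("g", i), ordinal = 1L, contig_id = id, start = s0,
      end = s0 + 120L, strand = "+", frame_offset = 0L, tstart = 0L,
      tend = 120L))
  }
  class(mods) <- c("mm_modules", "data.frame")
  list(contigs = ctgs, modules = mods)
}

test_that("recurrent flanks obey the >100 bp and >90% identity thresholds", {
  fx <- make_classified_set(21, n = 3, motif_len = 150)
  fl <- find_recurrent_flanks(fx$contigs, fx$modules)
  expect_gte(nrow(fl$motifs), 2L)  # one group per side
  expect_true(all(fl$motifs$support == 3L))

  ## 95 bp shared block: below the >100 bp rule
  fx2 <- make_classified_set(22, n = 3, motif_len = 95)
  fl2 <- find_recurrent_flanks(fx2$contigs, fx2$modules)
  expect_true(all(is.na(fl2$arrays$up_motif)))

  ## 150 bp at ~75% identity: below the >90% rule (at identities just
  ## under 0.9 a shorter internal sub-block can still legitimately satisfy
  ## the >100 bp / >90% definition)
  fx3 <- make_classified_set(23, n = 3, motif_len = 150,
                             motif_identity = 0.75)
  fl3 <- find_recurrent_flanks(fx3$contigs, fx3$modules)
  expect_true(all(is.na(fl3$arrays$up_motif)))
})

test_that("chromosome classes are recovered with ARI 1 on simulations", {
  skip_if_not_installed("mclust")
  for (s in 1:3) {
    sim <- simulate_dataset(small_cfg(s))
    ann <- annotate_transcripts(sim$truth$mature, sim$contigs)
    cls <- classify_chromosomes(sim$contigs, ann$modules)
    m <- merge(cls$classes, sim$truth$classes, by = "contig_id")
    expect_equal(mclust::adjustedRandIndex(m$class.x, m$class.y), 1,
                 info = paste("seed", s))
    ## labels are assigned by descending member count
    tab <- table(m$class.x[m$class.x != "U"])
    expect_true(all(diff(as.integer(tab[order(names(tab))])) <= 0))
  }
})

test_that("a contig mixing motifs of two classes is flagged hybrid", {
  sim <- simulate_dataset(small_cfg(4))
  tc <- sim$truth$classes
  labs <- setdiff(unique(tc$class), "U")
  skip_if(length(labs) < 2)
  memA <- tc$contig_id[tc$class == labs[1]][1]
  memB <- tc$contig_id[tc$class == labs[2]][1]
  casA <- sim$truth$cassettes[sim$truth$cassettes$contig_id == memA, ][1, ]
  casB <- sim$truth$cassettes[sim$truth$cassettes$contig_id == memB, ][1, ]
  upA <- substr(sim$contigs[[memA]]$seq, casA$start - 399, casA$start)
  dnB <- substr(sim$contigs[[memB]]$seq, casB$end + 1, casB$end + 400)
  mod <- random_seq(150)
  chim <- contig("HY01", paste0(random_seq(1500), upA, random_seq(60), mod,
                                random_seq(60), dnB, random_seq(1500)),
                 circular = TRUE)
  ctgs <- c(sim$contigs, list(HY01 = chim))
  ann <- annotate_transcripts(sim$truth$mature, sim$contigs)
  mods <- rbind(ann$modules, data.frame(
    gene = "orphanX", ordinal = 1L, contig_id = "HY01",
    start = 1500L + 400L + 60L, end = 1500L + 400L + 60L + 150L, strand = "+",
    frame_offset = 0L, tstart = 0L, tend = 150L))
  fl <- find_recurrent_flanks(ctgs, mods)
  gr <- group_into_classes(ctgs, fl)
  row <- gr$classes[gr$classes$contig_id == "HY01", ]
  expect_equal(row$class, "U")
  expect_true(row$hybrid)
})

test_that("cassette boundaries match a sliding-window identity oracle", {
  set.seed(25)
  shared1 <- random_seq(700); shared2 <- random_seq(700)
  insA <- random_seq(400); insB <- random_seq(380)
  a <- paste0(shared1, insA, shared2)
  b <- paste0(shared1, insB, shared2)
  ctgs <- list(a = contig("a", a), b = contig("b", b))
  dc <- delimit_cassettes(ctgs, c("a", "b"))
  ca <- dc$cassettes[dc$cassettes$contig_id == "a", ]
  expect_equal(nrow(ca), 1L)
  ## the low-identity run must cover the insert (within smoothing slack)
  expect_lte(ca$start, 710L)
  expect_gte(ca$end, 1090L)
  expect_lt(ca$end - ca$start, 400L + 220L)

  ## oracle: exhaustive trailing-window identity profile over the anchored
  ## per-base match vector
  prof <- mitomosaic:::match_profile(a, b)$prof
  w <- 100L
  wm <- vapply(w:length(prof), function(i) mean(prof[(i - w + 1L):i]), 0)
  below <- which(wm < 0.9) + w - 1L
  expect_true(min(below) >= ca$start - w && max(below) <= ca$end + w)
})

test_that("bi-cassette chromosomes yield two cassettes per contig", {
  ## bi-cassette chromosomes need constant segments longer than the motif
  ## search window on both arcs between the two opposed cassettes
  sim <- simulate_dataset(small_cfg(5, n_genes = 8L, n_classes = 2L,
                                    constant_region_length_range = c(3000L, 4500L),
                                    multi_cassette_fraction = 0.5,
                                    unclassified_fraction = 0))
  tc <- sim$truth$cassettes
  two <- names(which(table(tc$contig_id) == 2L))
  skip_if(length(two) < 2)
  ann <- annotate_transcripts(sim$truth$mature, sim$contigs)
  cls <- classify_chromosomes(sim$contigs, ann$modules)
  got <- table(cls$cassettes$contig_id)
  expect_true(all(got[two] == 2L))
})

test_that("architecture totals are conserved", {
  sim <- simulate_dataset(small_cfg(6, n_genes = 8L,
                                    modules_per_cassette_max = 4L,
                                    multi_module_cassette_fraction = 0.3))
  ann <- annotate_transcripts(sim$truth$mature, sim$contigs)
  cls <- classify_chromosomes(sim$contigs, ann$modules)
  tot <- cls$summary$totals
  expect_equal(tot$n_modules, nrow(ann$modules))
  expect_equal(tot$mono_module + tot$multi_module + tot$multi_cassette,
               tot$n_chromosomes)
  expect_equal(sum(cls$summary$per_contig$class == "U"), tot$unclassified)
  ## a six-module array counts as multi-module
  arr <- cls$summary$per_contig[cls$summary$per_contig$n_modules >= 2L, ]
  expect_true(all(arr$category %in% c("multi-module", "multi-cassette")))
})

test_that("chimeric contigs split at the coverage step", {
  set.seed(27)
  mito <- random_seq(3000); nuc <- random_seq(2000)
  cov <- c(rnorm(3000, 250, 10), rnorm(2000, 5, 1))
  ctg <- contig("x", paste0(mito, nuc), coverage = pmax(0, cov))
  parts <- split_chimeric(ctg)
  expect_equal(length(parts), 2L)
  expect_equal(parts[[1]]$label, "mito-candidate")
  expect_equal(parts[[2]]$label, "non-mito")
  expect_lte(abs(parts[[1]]$range[2] - 3000L), 50L)

  ## uniform coverage: no split
  ctg2 <- contig("y", random_seq(4000), coverage = rep(300, 4000))
  expect_equal(length(split_chimeric(ctg2)), 1L)

  ## noisy step (sd = 10%) still within +-50 bp
  cov3 <- c(rnorm(2500, 250, 25), rnorm(2500, 5, 0.5))
  ctg3 <- contig("z", random_seq(5000), coverage = pmax(0, cov3))
  parts3 <- split_chimeric(ctg3)
  expect_equal(length(parts3), 2L)
  expect_lte(abs(parts3[[1]]$range[2] - 2500L), 50L)

  ## no coverage: warn and leave unsplit
  expect_warning(split_chimeric(contig("w", random_seq(1000))), "coverage")
})

test_that("raising the identity threshold never increases motif support", {
  fx <- make_classified_set(28, n = 4, motif_len = 150,
                            motif_identity = 0.93)
  s1 <- find_recurrent_flanks(fx$contigs, fx$modules, min_identity = 0.90)
  s2 <- find_recurrent_flanks(fx$contigs, fx$modules, min_identity = 0.97)
  sup <- function(x) if (nrow(x$motifs)) sum(x$motifs$support) else 0L
  expect_lte(sup(s2), sup(s1))
})
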