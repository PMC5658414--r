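test_that("identical seed and config give byte-identical output", {
  a <- simulate_dataset(small_cfg(7))
  b <- simulate_dataset(small_cfg(7))
  expect_identical(vapply(a$contigs, `[[`, "", "seq"),
                   vapply(b$contigs, `[[`, "", "seq"))
  expect_identical(a$fragments, b$fragments)
  expect_identical(a$truth$mature, b$truth$mature)
  expect_identical(a$truth$modules, b$truth$modules)
  c <- simulate_dataset(small_cfg(8))
  expect_false(identical(a$fragments, c$fragments))
})

test_that("truth is self-consistent: genome plus editing reproduces transcripts", {
  for (s in 1:3) {
    sim <- simulate_dataset(small_cfg(s))
    expect_true(verify_truth(sim$truth, sim$contigs))
    ## every module lies inside exactly one cassette
    mods <- sim$truth$modules
    cas <- sim$truth$cassettes
    inside <- vapply(seq_len(nrow(mods)), function(i) {
      cc <- cas[cas$contig_id == mods$contig_id[i], , drop = FALSE]
      sum(mods$start[i] >= cc$start & mods$end[i] <= cc$end)
    }, 0L)
    expect_true(all(inside == 1L))
  }
})

test_that("gene fragmentation tiles the gene within the length bounds", {
  set.seed(1)
  cuts <- plan_fragmentation(300L, 3L, c(40L, 550L))
  expect_equal(cuts[1], 0L)
  expect_equal(cuts[length(cuts)], 300L)
  expect_true(all(diff(cuts) >= 40L & diff(cuts) <= 550L))
  expect_error(plan_fragmentation(100L, 3L, c(40L, 550L)), "infeasible")
  ## sampler stays within bounds over many draws
  lens <- unlist(lapply(1:1000, function(i)
    diff(plan_fragmentation(800L, 4L, c(40L, 550L)))))
  expect_true(all(lens >= 40L & lens <= 550L))
  expect_equal(sum(lens), 1000L * 800L / 250L * 250L)
})

test_that("unedit/apply editing are exact inverses", {
  expect_equal(unedit_sequence("ACGTTT", data.frame(
    kind = "U-append", pos = 3L, len = 3L)), "ACG")
  expect_equal(unedit_sequence("AGG", data.frame(
    kind = "A-to-I", pos = 1L, len = NA)), "AAG")
  expect_error(unedit_sequence("AGG", data.frame(
    kind = "A-to-I", pos = 0L, len = NA)), "non-G")
  set.seed(5)
  for (i in 1:25) {
    seg <- random_seq(120)
    segv <- strsplit(seg, "")[[1]]
    gpos <- which(segv == "G"); tpos <- which(segv == "T")
    ev <- rbind(
      if (length(gpos)) data.frame(kind = "A-to-I",
                                   pos = sample(gpos, 1) - 1L, len = NA),
      if (length(tpos) && max(tpos) < 120)
        data.frame(kind = "C-to-U", pos = sample(tpos, 1) - 1L, len = NA))
    ev <- ev[!duplicated(ev$pos), , drop = FALSE]
    tr <- rint_free <- paste0(seg, strrep("T", 4))
    ev2 <- rbind(ev, data.frame(kind = "U-append", pos = 120L, len = 4L))
    genomic <- unedit_sequence(tr, ev2)
    expect_equal(apply_editing(genomic, ev2), tr)
  }
})

test_that("the mono-module preset puts one module on every chromosome", {
  sim <- simulate_dataset(small_cfg(9, unclassified_fraction = 0))
  tab <- table(sim$truth$modules$contig_id)
  expect_true(all(tab == 1L))
  expect_equal(length(sim$contigs), nrow(sim$truth$modules))
  ## zero unclassified fraction: every contig carries a class label
  expect_true(all(sim$truth$classes$class != "U"))
})

test_that("multi-module arrays and nesting follow the configured architecture", {
  sim <- simulate_dataset(small_cfg(10, n_genes = 8L,
                                    modules_per_cassette_max = 6L,
                                    multi_module_cassette_fraction = 0.4,
                                    nesting_events = 1L))
  cas <- sim$truth$cassettes
  expect_true(any(cas$n_modules >= 2L))
  expect_true(all(cas$n_modules <= 6L))
  ## arrays combine modules of different genes
  mods <- sim$truth$modules
  multi <- cas[cas$n_modules >= 2L, ]
  for (k in seq_len(nrow(multi))) {
    mm <- mods[mods$contig_id == multi$contig_id[k] &
                 mods$start >= multi$start[k] & mods$end <= multi$end[k], ]
    expect_equal(length(unique(mm$gene)), nrow(mm))
  }
  ## nested pair is same-strand and in frame
  ne <- sim$truth$nesting[[1]]
  h <- mods[mods$gene == ne$host_gene & mods$ordinal == ne$host_ord, ]
  b <- mods[mods$gene == ne$emb_gene & mods$ordinal == ne$emb_ord, ]
  expect_equal(h$contig_id, b$contig_id)
  expect_true(b$start >= h$start && b$end <= h$end)
  expect_equal(h$strand, b$strand)
})

test_that("class members share >90% identical flanking motifs", {
  sim <- simulate_dataset(small_cfg(11))
  cls <- sim$truth$classes
  for (lab in setdiff(unique(cls$class), "U")) {
    mem <- cls$contig_id[cls$class == lab]
    if (length(mem) < 2) next
    cas <- sim$truth$cassettes
    ## motif region: 150 bp upstream of each member's cassette
    ups <- vapply(mem, function(id) {
      c0 <- cas[cas$contig_id == id, ][1, ]
      substr(sim$contigs[[id]]$seq, c0$start - 149, c0$start)
    }, "")
    for (i in 2:length(ups)) {
      idp <- mean(strsplit(ups[1], "")[[1]] == strsplit(ups[i], "")[[1]])
      expect_gt(idp, 0.9)
    }
  }
})

test_that("infeasible configurations are rejected with a diagnostic", {
  expect_error(simulate_dataset(small_cfg(1, gene_length_range = c(40L, 40L),
                                          modules_per_gene_range = c(2L, 2L))),
               "infeasible")
  expect_error(sim_config(bogus_key = 1), "unknown config keys")
})
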