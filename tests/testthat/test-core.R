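test_that("circular interval normalization preserves length and wraps", {
  iv <- interval("c", 5, 9)
  nv <- normalize_circular_interval(iv, 10L)
  expect_equal(c(nv$start, nv$end), c(5L, 9L))
  expect_false(nv$wraps)

  nv <- normalize_circular_interval(interval("c", 8, 13), 10L)
  expect_equal(c(nv$start, nv$end), c(8L, 13L))
  expect_true(nv$wraps)

  nv <- normalize_circular_interval(interval("c", 12, 15), 10L)
  expect_equal(c(nv$start, nv$end), c(2L, 5L))

  expect_error(normalize_circular_interval(interval("c", 0, 11), 10L),
               "exceeds")
})

test_that("wrap-aware extraction covers the origin and round-trips", {
  ctg <- contig("c", "AACCGGTTAC", circular = TRUE)
  ## bases 8,9,0,1,2 of AACCGGTTAC = A,C,A,A,C
  expect_equal(extract_interval(ctg, interval("c", 8, 13)), "ACAAC")
  expect_equal(extract_interval(ctg, interval("c", 8, 13, "-")),
               reverse_complement("ACAAC"))
  expect_equal(extract_interval(ctg, interval("c", 2, 6)), "CCGG")
})

test_that("reverse complement is the Watson-Crick involution", {
  expect_equal(reverse_complement("ACGT"), "ACGT")
  expect_equal(reverse_complement("AAAC"), "GTTT")
  set.seed(42)
  for (i in 1:20) {
    s <- random_seq(sample(5:60, 1))
    expect_equal(reverse_complement(reverse_complement(s)), s)
  }
  expect_error(reverse_complement("ACGU"), "outside")
})

test_that("translation follows the selected genetic code", {
  expect_equal(translate_seq("ATGGCT"), "MA")
  ## a uridine tract reads as a phenylalanine tract
  expect_equal(translate_seq("TTTTTTTTT"), "FFF")
  ## trailing partial codon dropped
  expect_equal(translate_seq("ATGGCTA"), "MA")
  ## TGA is stop in the standard code, Trp in the protozoan
  ## mitochondrial code (NCBI table 4)
  expect_equal(translate_seq("ATGTGA", code = "standard"), "M*")
  expect_equal(translate_seq("ATGTGA", code = "protozoan_mito"), "MW")
})

test_that("minus-strand module translation matches the transcript segment", {
  sim <- simulate_dataset(small_cfg(2))
  mods <- sim$truth$modules
  prot <- mods[!is.na(mods$frame_offset) & mods$strand == "-", ]
  skip_if(nrow(prot) == 0)
  r <- prot[1, , drop = FALSE]
  gseq <- module_seq(r, sim$contigs, 1)
  tseg <- substr(sim$truth$mature[[r$gene]], r$tstart + 1, r$tend)
  ## genomic (unedited) and transcript segments agree at non-edited sites;
  ## translation in the module frame must agree outside editing positions
  phase <- (3 - r$frame_offset) %% 3
  if (nchar(gseq) - phase >= 3) {
    aa_g <- translate_seq(substr(gseq, phase + 1, nchar(gseq)))
    aa_t <- translate_seq(substr(tseg, phase + 1, nchar(tseg)))
    expect_equal(nchar(aa_g), nchar(aa_t))
    agree <- mean(strsplit(aa_g, "")[[1]] == strsplit(aa_t, "")[[1]])
    expect_gte(agree, 0.8)  # differences only at edited codons
  }
})
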