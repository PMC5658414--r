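test_that("overlap_align finds flank-tolerant dovetails and containments", {
  core <- "ACGGTTACCAGTTGACGTTA"  # 20-mer core
  a <- paste0("GGGG", core)
  b <- paste0(core, "CCCC")
  ov <- overlap_align(a, b, min_overlap = 8L, max_end_skip = 4L)
  expect_false(is.null(ov))
  expect_equal(substr(a, ov$a_start, ov$a_end), core)
  expect_equal(substr(b, ov$b_start, ov$b_end), core)
  expect_equal(unname(ov$ends["la"]), 4L)
  expect_equal(unname(ov$ends["rb"]), 4L)

  ## identical fragments: full-length containment
  s <- random_seq(80, seed = 2)
  ov <- overlap_align(s, s)
  expect_equal(ov$cols, 80L)
  expect_equal(ov$identity, 1)

  ## flanks on both inner ends are tolerated up to max_end_skip
  set.seed(3)
  tr <- random_seq(300)
  fa <- paste0(substr(tr, 1, 150), random_seq(30))   # 3' flank junk
  fb <- paste0(random_seq(25), substr(tr, 101, 300)) # 5' flank junk
  ov <- overlap_align(fa, fb, min_overlap = 20L, max_end_skip = 60L)
  expect_false(is.null(ov))
  expect_equal(ov$cols, 50L)  # true shared region 101..150

  ## random sequences share no qualifying overlap
  set.seed(4)
  nulls <- vapply(1:20, function(i)
    is.null(overlap_align(random_seq(100), random_seq(100),
                          min_overlap = 20L, min_identity = 0.95)), TRUE)
  expect_true(all(nulls))
})

test_that("overlap alignment matches brute-force local DP on short pairs", {
  set.seed(6)
  for (i in 1:30) {
    core <- random_seq(sample(25:80, 1))
    a <- paste0(random_seq(sample(0:40, 1)), core, random_seq(sample(0:40, 1)))
    b <- paste0(random_seq(sample(0:40, 1)), core, random_seq(sample(0:40, 1)))
    stopifnot(nchar(a) <= 200, nchar(b) <= 200)
    want <- sw_oracle(a, b)
    got <- mitomosaic:::olap_align_cpp(a, b)
    expect_equal(got$score, want)
  }
})

test_that("layout consensus reconstructs a single fragment as itself", {
  f <- c(x = random_seq(150, seed = 7))
  tr <- layout_consensus(f, list())
  expect_equal(tr[[1]]$seq, unname(f))
  expect_equal(tr[[1]]$members, "x")
})

test_that("error-free pools reconstruct every transcript exactly", {
  for (s in 1:3) {
    sim <- simulate_dataset(small_cfg(s, splice_error_rates = c(0, 0, 0, 0)))
    tr <- reconstruct_transcripts(sim$fragments)
    got <- vapply(tr, `[[`, "", "seq")
    expect_true(all(unname(sim$truth$mature) %in% got),
                info = paste("seed", s))
  }
})

test_that("a mis-joined chimeric fragment is set aside and consensus stays exact", {
  sim <- simulate_dataset(small_cfg(3))
  errs <- sim$truth$injected_errors
  skip_if(nrow(errs) == 0)
  tr <- reconstruct_transcripts(sim$fragments)
  got <- vapply(tr, `[[`, "", "seq")
  expect_true(all(unname(sim$truth$mature) %in% got))
})

test_that("reconstruction is idempotent", {
  sim <- simulate_dataset(small_cfg(2, splice_error_rates = c(0, 0, 0, 0)))
  tr <- reconstruct_transcripts(sim$fragments)
  got <- vapply(tr, `[[`, "", "seq")
  again <- reconstruct_transcripts(got, min_members = 1L)
  expect_setequal(vapply(again, `[[`, "", "seq"), unname(got))
})

test_that("iterative extension recovers missing terminal modules", {
  sim <- simulate_dataset(small_cfg(5, splice_error_rates = c(0, 0, 0, 0)))
  m <- sim$truth$mature[[which.max(nchar(sim$truth$mature))]]
  seedt <- substr(m, 1, nchar(m) - 60)
  ext <- iterative_extend(seedt, sim$fragments)
  expect_equal(ext, m)
  ## a full-length seed is a fixed point
  expect_equal(iterative_extend(m, sim$fragments), m)
  ## rounds_max = 0 returns the seed unchanged
  expect_equal(iterative_extend(seedt, sim$fragments, rounds_max = 0L), seedt)
})

test_that("poly-A tails are trimmed only above the run threshold", {
  expect_equal(trim_polya("ACGTAAAAA")$seq, "ACGT")
  expect_equal(trim_polya("ACGTAAAAA")$tail, 5L)
  expect_equal(trim_polya("ACGTAAA")$seq, "ACGTAAA")
  expect_equal(trim_polya("AAAAAACGT")$seq, "AAAAAACGT")
})
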