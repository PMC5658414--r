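test_that("ortholog MSA handles identity, gaps and the width property", {
  s <- c(a = "ACGTACGTAGCCTA", b = "ACGTACGTAGCCTA", c = "ACGTACGTAGCCTA")
  al <- build_ortholog_msa(s)
  expect_true(all(nchar(al) == 14L))
  expect_false(any(grepl("-", al)))

  set.seed(40)
  base <- random_seq(60)
  del <- paste0(substr(base, 1, 30), substr(base, 34, 60))
  al2 <- build_ortholog_msa(c(a = base, b = del))
  expect_equal(nchar(al2[["a"]]), 60L)
  expect_equal(sum(strsplit(al2[["b"]], "")[[1]] == "-"), 3L)
  ## gap content must reproduce both inputs
  expect_equal(gsub("-", "", al2[["a"]]), base)
  expect_equal(gsub("-", "", al2[["b"]]), del)
  ## alignment length >= max input length
  expect_gte(nchar(al2[["a"]]), max(nchar(base), nchar(del)))
  expect_error(build_ortholog_msa(character(0)), "two sequences")
})

test_that("breakpoints project to columns with shifts in ungapped nt", {
  set.seed(41)
  base <- random_seq(400)
  seqs <- c(s1 = base, s2 = base, s3 = base, s4 = base)
  msa <- build_ortholog_msa(seqs)
  jn <- list(s1 = c(100L, 200L, 300L), s2 = c(100L, 200L, 300L),
             s3 = c(100L, 200L, 300L), s4 = c(100L, 203L, 300L))
  bp <- project_breakpoints(msa, jn)
  g200 <- bp$map$group[bp$map$offset == 200L & bp$map$species == "s1"]
  sel <- bp$map[bp$map$group == g200, ]
  expect_equal(nrow(sel), 4L)
  expect_equal(sort(unique(abs(sel$shift))), c(0L, 3L))
  expect_equal(abs(sel$shift[sel$species == "s4"]), 3L)
  ## identical junction columns match with zero shift
  g100 <- bp$map$group[bp$map$offset == 100L][1]
  expect_true(all(bp$map$shift[bp$map$group == g100] == 0L))
  ## a species-specific junction beyond the window stays unmatched
  jn2 <- list(s1 = c(100L), s2 = c(100L, 250L))
  bp2 <- project_breakpoints(msa[c("s1", "s2")], jn2)
  g250 <- bp2$map$group[bp2$map$offset == 250L]
  expect_equal(sum(bp2$map$group == g250), 1L)
})

test_that("module fusion is detected from a missing junction", {
  set.seed(42)
  base <- random_seq(500)
  msa <- build_ortholog_msa(c(ref = base, fused = base))
  jn <- list(ref = c(100L, 200L, 300L, 400L), fused = c(200L, 300L, 400L))
  bp <- project_breakpoints(msa, jn)
  ev <- detect_fusion_fission(bp, gene = "y3")
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$species_without, "fused")
  expect_equal(ev$ordinal, 1L)
  ## identical breakpoint sets: no events
  bp0 <- project_breakpoints(msa, list(ref = c(100L, 200L),
                                       fused = c(100L, 200L)))
  expect_equal(nrow(detect_fusion_fission(bp0)), 0L)
  ## symmetry: swapping species swaps roles but keeps the event count
  bp_sw <- project_breakpoints(msa, rev(jn))
  ev_sw <- detect_fusion_fission(bp_sw, gene = "y3")
  expect_equal(nrow(ev_sw), nrow(ev))
  expect_equal(ev_sw$species_without, "fused")
})

test_that("shared editing sites and clusters are tabulated per column", {
  set.seed(43)
  base <- random_seq(300)
  msa <- build_ortholog_msa(c(a = base, b = base, c = base, d = base))
  ed <- list(
    a = data.frame(kind = c("U-append", "A-to-I", "A-to-I"),
                   tpos = c(50L, 120L, 130L), len = c(10L, NA, NA)),
    b = data.frame(kind = c("U-append", "A-to-I", "A-to-I"),
                   tpos = c(50L, 120L, 130L), len = c(12L, NA, NA)),
    c = data.frame(kind = "U-append", tpos = 50L, len = 8L),
    d = data.frame(kind = "U-append", tpos = 50L, len = 9L))
  sh <- shared_editing(ed, msa)
  u <- sh$sites[sh$sites$kind == "U-append", ]
  expect_equal(u$n_species, 4L)
  cl <- sh$clusters
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_species, 2L)
  expect_equal(cl$species, "a,b")
})

test_that("mean pairwise identity excludes pair-gapped columns", {
  msa <- c(a = "ACGTACGTAC", b = "ACGTACGTAC")
  expect_equal(mean_pairwise_identity(msa), 100.0)
  msa2 <- c(a = "ACGTACGTAC", b = "ACGTACGTAT")
  expect_equal(mean_pairwise_identity(msa2), 90.0)
  ## permutation invariance
  set.seed(44)
  seqs <- setNames(vapply(1:4, function(i)
    mitomosaic:::mutate_seq(random_seq(100, seed = 45), 0.1), ""),
    c("a", "b", "c", "d"))
  msa3 <- build_ortholog_msa(seqs)
  v1 <- mean_pairwise_identity(msa3)
  v2 <- mean_pairwise_identity(msa3[c(3, 1, 4, 2)])
  expect_equal(v1, v2)
  ## brute-force oracle on the same alignment
  ch <- lapply(msa3, function(x) strsplit(x, "")[[1]])
  vals <- c()
  for (i in 1:3) for (j in (i + 1):4) {
    ok <- ch[[i]] != "-" & ch[[j]] != "-"
    vals <- c(vals, mean(ch[[i]][ok] == ch[[j]][ok]))
  }
  expect_equal(v1, round(100 * mean(vals), 1))
  ## gap-only region is flagged undefined
  expect_warning(ret <- mean_pairwise_identity(c(a = "AC--", b = "AC--"),
                                               region = 3:4), "comparable")
  expect_true(is.na(ret))
})
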