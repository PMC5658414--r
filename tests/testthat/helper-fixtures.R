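## Shared fixtures and independent oracles.
## Unit tests run on a scaled-down genome (6-8 genes, 1.2-2.5 kbp
## chromosomes) so the whole suite stays fast; the acceptance tests use the
## full-scale presets.

small_cfg <- function(seed, ...) {
  sim_config(n_genes = 6L, constant_region_length_range = c(1200L, 2500L),
             seed = seed, ...)
}

## brute-force Smith-Waterman (plain R), independent of the package's
## alignment kernel; returns the best local score
sw_oracle <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  S <- matrix(0, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      sc <- max(0,
                S[i - 1, j - 1] + ifelse(av[i - 1] == bv[j - 1], match, mismatch),
                S[i - 1, j] + gap,
                S[i, j - 1] + gap)
      S[i, j] <- sc
      if (sc > best) best <- sc
    }
  }
  best
}

## independent single-linkage check: a clustering is the unique single-
## linkage result iff consecutive in-cluster gaps are <= max_gap and
## between-cluster gaps exceed it
cluster_oracle <- function(pos, max_gap, min_sites) {
  pos <- sort(pos)
  grp <- cumsum(c(1, as.integer(diff(pos) > max_gap)))
  keep <- table(grp) >= min_sites
  lapply(names(keep)[keep], function(g) pos[grp == as.integer(g)])
}

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## longest common substring length (rolling-row DP)
lcs_substring <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  prev <- integer(length(bv))
  best <- 0L
  for (i in seq_along(av)) {
    cur <- ifelse(av[i] == bv, c(0L, prev[-length(prev)]) + 1L, 0L)
    best <- max(best, max(cur))
    prev <- cur
  }
  best
}
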