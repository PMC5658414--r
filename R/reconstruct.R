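## Overlap-layout-consensus reconstruction of mature trans-spliced
## transcripts from pools of partial, possibly flank-carrying fragments.

#' Trim a 3' poly-A tail
#'
#' Removes a terminal run of >= `min_run` A residues (the oligo-dT-captured
#' polyadenylation tail of mature mRNAs); shorter terminal A runs are kept
#' as potentially genome-encoded.
#'
#' @param seq Fragment sequence.
#' @param min_run Minimum run length treated as a tail.
#' @return list(seq, tail) with the trimmed sequence and tail length.
#' @export
trim_polya <- function(seq, min_run = 5L) {
  m <- regmatches(seq, regexpr("A+$", seq))
  tl <- if (length(m)) nchar(m) else 0L
  if (tl >= min_run) list(seq = substr(seq, 1L, nchar(seq) - tl), tail = tl)
  else list(seq = seq, tail = 0L)
}

seq_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1L), k:n)
}

## most common shared k-mer diagonal between two sequences (a_pos - b_pos),
## or NULL when they share no k-mer
anchor_diagonal <- function(a, b, k = 14L) {
  ka <- seq_kmers(a, k); kb <- seq_kmers(b, k)
  hit <- match(ka, kb)
  ia <- which(!is.na(hit))
  if (!length(ia)) return(NULL)
  diffs <- ia - hit[ia]
  as.integer(names(sort(table(diffs), decreasing = TRUE))[1])
}

#' Best dovetail/containment overlap between two fragments
#'
#' Ends-free pairwise alignment (linear gap costs) whose aligned core must
#' reach `min_overlap` and `min_identity`; up to `max_end_skip` unaligned
#' bases are tolerated at the fragment ends facing into the overlap -- the
#' poorly aligning 5'/3' flanks of unprocessed precursor modules.
#'
#' @param a,b Fragment sequences (character).
#' @param min_overlap Minimum aligned core length (nt).
#' @param min_identity Minimum identity over aligned columns (gaps count as
#'   mismatches).
#' @param max_end_skip Maximum tolerated unaligned length at an inner end.
#' @param names_ab Optional c(name_a, name_b) recorded in the result.
#' @return An `mm_overlap` list, or `NULL` if no qualifying overlap.
#' @export
overlap_align <- function(a, b, min_overlap = 20L, min_identity = 0.98,
                          max_end_skip = 60L, names_ab = c("a", "b"),
                          diag = NULL) {
  stopifnot(nchar(a) > 0L, nchar(b) > 0L)
  if (is.null(diag)) diag <- anchor_diagonal(a, b)
  na <- nchar(a); nb <- nchar(b)
  if (is.null(diag)) {
    if (max(na, nb) > 1000L) return(NULL)
    al <- olap_align_cpp(a, b)
  } else {
    ## restrict the banded DP to the diagonal overlap window (plus margin
    ## covering flanks and small indels); ends outside it are free anyway
    mar <- max_end_skip + 16L
    A1 <- max(1L, 1L + diag); A2 <- min(na, nb + diag)
    if (A2 - A1 + 1L < min_overlap) return(NULL)
    a_lo <- max(1L, A1 - mar); a_hi <- min(na, A2 + mar)
    b_lo <- max(1L, A1 - diag - mar); b_hi <- min(nb, A2 - diag + mar)
    al <- olap_align_cpp(substr(a, a_lo, a_hi), substr(b, b_lo, b_hi),
                         band_center = diag - (a_lo - 1L) + (b_lo - 1L),
                         band_width = 48L)
    off_a <- a_lo - 1L; off_b <- b_lo - 1L
    al$a_start <- al$a_start + off_a; al$a_end <- al$a_end + off_a
    al$b_start <- al$b_start + off_b; al$b_end <- al$b_end + off_b
    al$a_idx <- al$a_idx + off_a; al$b_idx <- al$b_idx + off_b
  }
  if (al$cols < min_overlap) return(NULL)
  ## the raw optimum may creep marginally into unprocessed-flank junk at
  ## an end; keep the best high-identity core segment instead
  av <- chars(a); bv <- chars(b)
  mvec <- !is.na(al$a_idx) & !is.na(al$b_idx) &
    av[ifelse(is.na(al$a_idx), 1L, al$a_idx)] ==
      bv[ifelse(is.na(al$b_idx), 1L, al$b_idx)]
  sc <- ifelse(mvec, 1, -19)
  cs <- cumsum(sc)
  pre <- cummin(c(0, cs[-length(cs)]))
  be <- which.max(cs - pre)
  bs <- which(c(0, cs)[seq_len(be)] == pre[be])[1]
  seg <- bs:be
  ai <- al$a_idx[seg]; bi <- al$b_idx[seg]
  if (all(is.na(ai)) || all(is.na(bi))) return(NULL)
  al$a_start <- min(ai, na.rm = TRUE); al$a_end <- max(ai, na.rm = TRUE)
  al$b_start <- min(bi, na.rm = TRUE); al$b_end <- max(bi, na.rm = TRUE)
  al$cols <- length(seg); al$matches <- sum(mvec[seg])
  al$a_idx <- ai; al$b_idx <- bi
  if (al$cols < min_overlap) return(NULL)
  identity <- al$matches / al$cols
  if (identity < min_identity) return(NULL)
  ## a core dominated by one homopolymer (a poly-U tract plus a few chance
  ## bases) is not evidence of common origin: demand informative columns
  core_a <- chars(substr(a, al$a_start, al$a_end))
  informative <- length(core_a) - max(rle(core_a)$lengths)
  if (informative < 15L) return(NULL)
  la <- al$a_start - 1L; ra <- nchar(a) - al$a_end
  lb <- al$b_start - 1L; rb <- nchar(b) - al$b_end
  if (min(la, lb) > max_end_skip || min(ra, rb) > max_end_skip) return(NULL)
  ## placement offset from the modal aligned diagonal: robust against a
  ## stray gap opened inside a precursor-flank end
  dd <- al$a_idx - al$b_idx
  dd <- dd[!is.na(dd)]
  off <- as.integer(names(sort(table(dd), decreasing = TRUE))[1])
  structure(list(frag_a = names_ab[1], frag_b = names_ab[2],
                 a_start = al$a_start, a_end = al$a_end,
                 b_start = al$b_start, b_end = al$b_end,
                 identity = identity, cols = al$cols, score = al$score,
                 ends = c(la = la, ra = ra, lb = lb, rb = rb),
                 offset = off),
            class = "mm_overlap")
}

#' All qualifying pairwise overlaps in a fragment pool
#'
#' Pairs are prefiltered by shared k-mers before alignment.
#'
#' @param frags Named character vector of (poly-A trimmed) fragments.
#' @param min_overlap,min_identity,max_end_skip See [overlap_align()].
#' @param k Prefilter k-mer size.
#' @return List of `mm_overlap` records.
#' @export
find_overlaps <- function(frags, min_overlap = 20L, min_identity = 0.98,
                          max_end_skip = 60L, k = 16L) {
  ids <- names(frags)
  ## k-mer -> fragment incidence (with first positions, so the prefilter
  ## also yields the anchor diagonal for the banded alignment)
  km <- lapply(frags, function(s) {
    x <- seq_kmers(s, k)
    ## low-complexity k-mers (mono/di-nucleotide repeats, e.g. U-tract
    ## poly-T) would pair fragments of unrelated genes
    keep <- !duplicated(x) & !low_complexity(x)
    data.frame(kmer = x[keep], pos = which(keep))
  })
  df <- data.frame(kmer = unlist(lapply(km, `[[`, "kmer")),
                   pos = unlist(lapply(km, `[[`, "pos")),
                   frag = rep(seq_along(frags), vapply(km, nrow, 0L)))
  cnt <- table(df$kmer)
  df <- df[df$kmer %in% names(cnt)[cnt >= 2L & cnt <= 40L], , drop = FALSE]
  prs <- do.call(rbind, lapply(split(df[, c("frag", "pos")], df$kmer),
                               function(grp) {
    o <- order(grp$frag)
    f <- grp$frag[o]; p <- grp$pos[o]
    cb <- utils::combn(length(f), 2L)
    cbind(i = f[cb[1, ]], j = f[cb[2, ]], d = p[cb[1, ]] - p[cb[2, ]])
  }))
  if (is.null(prs)) return(list())
  prs <- prs[prs[, "i"] != prs[, "j"], , drop = FALSE]
  key <- paste0(prs[, "i"], "_", prs[, "j"])
  ## require at least two shared k-mers (one shared k-mer between
  ## unrelated fragments is mostly chance) and keep the modal diagonal
  nshare <- table(key)
  keep <- which(!duplicated(key) & key %in% names(nshare)[nshare >= 2L])
  out <- list()
  for (r in keep) {
    i <- prs[r, "i"]; j <- prs[r, "j"]
    ov <- overlap_align(frags[[i]], frags[[j]], min_overlap, min_identity,
                        max_end_skip, names_ab = ids[c(i, j)],
                        diag = prs[r, "d"])
    if (!is.null(ov)) out[[length(out) + 1L]] <- ov
  }
  out
}

#' Layout and consensus over a fragment pool
#'
#' Orders overlap-connected fragments into layouts (containments absorbed)
#' and calls a per-column majority consensus over fragment cores.  A
#' fragment's core is the part corroborated by at least one accepted
#' overlap within its final layout; skipped precursor flanks therefore
#' never reach the consensus interior.  Placement uses a maximum-score
#' spanning forest; fragments whose placement conflicts with independent
#' overlaps (small indels from imprecise trans-splicing) are excluded, and
#' overlap edges that entangle sequence-incompatible camps (mis-joined
#' chimeric fragments, dual-purpose repeat regions shared by two genes)
#' are cut so each gene resolves into its own layout.
#'
#' @param frags Named character vector (poly-A trimmed).
#' @param overlaps List of `mm_overlap` from [find_overlaps()].
#' @param offset_tol Maximum placement disagreement (nt) before an overlap
#'   counts as conflicting.
#' @return List of `mm_transcript` objects, sorted by decreasing length then
#'   sequence; each has `seq`, `support`, `conflicts`, `members`, `excluded`.
#' @export
layout_consensus <- function(frags, overlaps, offset_tol = 0L) {
  ids <- names(frags)
  n <- length(frags)
  lens <- nchar(frags)
  edges <- data.frame(
    i = match(vapply(overlaps, `[[`, "", "frag_a"), ids),
    j = match(vapply(overlaps, `[[`, "", "frag_b"), ids),
    off = vapply(overlaps, function(o) as.integer(o$offset), 0L),
    score = vapply(overlaps, `[[`, 0, "score"),
    alive = rep(TRUE, length(overlaps)))
  ov_a <- vapply(overlaps, function(o) as.integer(o$a_start), 0L)
  ov_b <- vapply(overlaps, function(o) as.integer(o$a_end), 0L)
  ov_c <- vapply(overlaps, function(o) as.integer(o$b_start), 0L)
  ov_d <- vapply(overlaps, function(o) as.integer(o$b_end), 0L)
  excluded <- logical(n)
  placed <- rep(NA_integer_, n); comp <- rep(NA_integer_, n)
  tree <- logical(nrow(edges))
  inc <- vector("list", n)
  rebuild_inc <- function() {
    inc <<- vector("list", n)
    for (r in which(edges$alive)) {
      inc[[edges$i[r]]] <<- c(inc[[edges$i[r]]], r)
      inc[[edges$j[r]]] <<- c(inc[[edges$j[r]]], r)
    }
  }
  rebuild_inc()

  place_all <- function() {
    ## maximum-score spanning forest (errors have lower-scoring overlaps,
    ## so clean edges carry the placement), offsets via the tree
    ord <- order(-edges$score)
    parent <- seq_len(n)
    findp <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    tree <<- logical(nrow(edges))
    for (r in ord) {
      if (!edges$alive[r]) next
      i <- edges$i[r]; j <- edges$j[r]
      pi <- findp(i); pj <- findp(j)
      if (pi != pj) { parent[pj] <- pi; tree[r] <<- TRUE }
    }
    placed <<- rep(NA_integer_, n); comp <<- rep(NA_integer_, n)
    adj <- vector("list", n)
    for (r in which(tree)) {
      adj[[edges$i[r]]] <- c(adj[[edges$i[r]]], list(c(edges$j[r], edges$off[r])))
      adj[[edges$j[r]]] <- c(adj[[edges$j[r]]], list(c(edges$i[r], -edges$off[r])))
    }
    ncomp <- 0L
    for (seed in order(-lens, ids)) {
      if (!is.na(comp[seed])) next
      ncomp <- ncomp + 1L
      comp[seed] <<- ncomp; placed[seed] <<- 0L
      queue <- seed
      while (length(queue)) {
        cur <- queue[1]; queue <- queue[-1]
        for (e in adj[[cur]]) {
          if (is.na(comp[e[1]])) {
            comp[e[1]] <<- ncomp
            placed[e[1]] <<- placed[cur] + e[2]
            queue <- c(queue, e[1])
          }
        }
      }
    }
    ncomp
  }

  ## phase 1: an overlap that contradicts the spanning-forest placement
  ## (indel-shifted mis-spliced fragments) is dropped; the fragment keeps
  ## contributing the side corroborated by its surviving overlaps
  for (round in 1:10) {
    place_all()
    bad_e <- which(edges$alive & !tree &
                     abs(placed[edges$j] - (placed[edges$i] + edges$off)) > offset_tol)
    if (!length(bad_e)) break
    edges$alive[bad_e] <- FALSE
    rebuild_inc()
  }

  ## unprocessed-flank junk at a fragment end aligns with nothing except
  ## the rare partner carrying the same flank; when several partners'
  ## alignments stop short of an end while the partners themselves
  ## continue, and almost nobody aligns through it, the end is junk and is
  ## barred from the consensus core
  left_bound <- rep(1L, n); right_bound <- lens
  trim_junk_ends <- function() {
    for (f in seq_len(n)) {
      sel <- inc[[f]]
      sel <- sel[edges$alive[sel]]
      if (length(sel) < 2L) next
      fi <- edges$i[sel] == f
      fe1 <- ifelse(fi, ov_a[sel], ov_c[sel])   # f's aligned start
      fe2 <- ifelse(fi, ov_b[sel], ov_d[sel])   # f's aligned end
      pl <- ifelse(fi, lens[edges$j[sel]], lens[edges$i[sel]])
      pe1 <- ifelse(fi, ov_c[sel], ov_a[sel])
      pe2 <- ifelse(fi, ov_d[sel], ov_b[sel])
      ## right side: partners disagreeing beyond C must outnumber partners
      ## aligning through (the rare partners carrying the same flank)
      dis <- which(lens[f] - fe2 > 5L & pl - pe2 > 20L)
      if (length(dis) >= 2L) {
        C <- max(fe2[dis])
        if (sum(fe2 > C + 5L) <= length(dis) %/% 2L)
          right_bound[f] <<- min(right_bound[f], C)
      }
      ## left side
      dis <- which(fe1 > 6L & pe1 > 21L)
      if (length(dis) >= 2L) {
        C <- min(fe1[dis])
        if (sum(fe1 < C - 5L) <= length(dis) %/% 2L)
          left_bound[f] <<- max(left_bound[f], C)
      }
    }
  }
  trim_junk_ends()

  core_span <- function(i, same_comp_only = FALSE) {
    sel <- inc[[i]]
    sel <- sel[edges$alive[sel]]
    if (same_comp_only)
      sel <- sel[comp[edges$i[sel]] == comp[edges$j[sel]]]
    if (!length(sel)) return(NULL)
    r1 <- ifelse(edges$i[sel] == i, ov_a[sel], ov_c[sel])
    r2 <- ifelse(edges$i[sel] == i, ov_b[sel], ov_d[sel])
    a <- max(min(r1), left_bound[i]); b <- min(max(r2), right_bound[i])
    if (b <= a) return(NULL)
    c(a, b)
  }
  seq_ident_at <- function(i, j, min_cols = 150L) {
    ci <- core_span(i); cj <- core_span(j)
    if (is.null(ci) || is.null(cj)) return(NA_real_)
    s1 <- max(placed[i] + ci[1] - 1L, placed[j] + cj[1] - 1L)
    s2 <- min(placed[i] + ci[2], placed[j] + cj[2])
    if (s2 - s1 < min_cols) return(NA_real_)
    a <- substr(frags[[i]], s1 - placed[i] + 1L, s2 - placed[i])
    b <- substr(frags[[j]], s1 - placed[j] + 1L, s2 - placed[j])
    mean(chars(a) == chars(b))
  }

  ## phase 2: camps of fragments whose placed cores disagree deeply must
  ## not share a layout (mis-joined chimeric fragments; dual-purpose
  ## repeat regions literally shared by two genes).  Starting from an
  ## incompatible pair, fragments are propagated into two camps: a
  ## fragment joins a camp it is connected to unless its placed core
  ## disagrees with a member; fragments compatible with both camps (cores
  ## confined to the shared region) follow their strongest edge; fragments
  ## disagreeing with both camps (chimeras) are isolated.  All edges
  ## between the camps are then cut.
  disagrees_with <- function(u, members) {
    for (m in members) {
      idt <- seq_ident_at(u, m, min_cols = 80L)
      if (!is.na(idt) && idt < 0.6) return(TRUE)
    }
    FALSE
  }
  split_camps <- function(mem, i, j) {
    camp <- setNames(rep(NA_character_, length(mem)), mem)
    camp[as.character(i)] <- "i"; camp[as.character(j)] <- "j"
    repeat {
      progress <- FALSE
      for (u in mem[is.na(camp[as.character(mem)])]) {
        sel <- inc[[u]]
        sel <- sel[edges$alive[sel]]
        if (!length(sel)) next
        nb <- ifelse(edges$i[sel] == u, edges$j[sel], edges$i[sel])
        sc <- edges$score[sel]
        cn <- camp[as.character(nb)]
        has_i <- any(!is.na(cn) & cn == "i")
        has_j <- any(!is.na(cn) & cn == "j")
        if (!has_i && !has_j) next
        mi <- as.integer(names(camp)[!is.na(camp) & camp == "i"])
        mj <- as.integer(names(camp)[!is.na(camp) & camp == "j"])
        di <- disagrees_with(u, mi)
        dj <- disagrees_with(u, mj)
        pick <- if (di && dj) "x"                       # chimera: isolate
        else if (has_i && !di && (dj || !has_j)) "i"
        else if (has_j && !dj && (di || !has_i)) "j"
        else if (has_i && has_j && !di && !dj) {
          ## shared-region fragment: follow the strongest edge
          if (max(sc[!is.na(cn) & cn == "i"]) >=
                max(sc[!is.na(cn) & cn == "j"])) "i" else "j"
        } else next
        camp[as.character(u)] <- pick
        progress <- TRUE
      }
      if (!progress) break
    }
    ## cut edges between camps (and isolate chimeras)
    ncut <- 0L
    for (r in which(edges$alive)) {
      ci <- camp[as.character(edges$i[r])]
      cj <- camp[as.character(edges$j[r])]
      if (is.na(ci) || is.na(cj)) next
      if (ci == "x" || cj == "x" || ci != cj) {
        edges$alive[r] <<- FALSE
        ncut <- ncut + 1L
      }
    }
    ncut
  }
  for (round in 1:20) {
    found <- FALSE
    for (cc in unique(comp[!is.na(comp)])) {
      mem <- which(comp == cc)
      if (length(mem) < 3L) next
      pairkey <- character(0)
      av <- which(edges$alive)
      if (length(av))
        pairkey <- paste0(pmin(edges$i[av], edges$j[av]), "_",
                          pmax(edges$i[av], edges$j[av]))
      for (x in seq_along(mem)[-length(mem)]) {
        for (y in (x + 1L):length(mem)) {
          i <- mem[x]; j <- mem[y]
          if (paste0(min(i, j), "_", max(i, j)) %in% pairkey) next
          idt <- seq_ident_at(i, j)
          ## flank-sharing precursors can disagree over a short stretch;
          ## only long, deep disagreement marks an entangled layout
          if (!is.na(idt) && idt < 0.55) {
            if (split_camps(mem, i, j) > 0L) found <- TRUE
          }
          if (found) break
        }
        if (found) break
      }
      if (found) break
    }
    if (!found) break
    rebuild_inc()
    place_all()
  }

  ## consensus per final component, cores restricted to surviving
  ## same-component overlaps
  ncomp <- max(c(0L, comp), na.rm = TRUE)
  out <- list()
  for (cc in seq_len(ncomp)) {
    mem <- which(comp == cc & !excluded)
    if (!length(mem)) next
    cores <- lapply(mem, function(f) {
      cs <- core_span(f, same_comp_only = TRUE)
      if (is.null(cs) && length(mem) == 1L) cs <- c(1L, lens[f])
      cs
    })
    keep <- !vapply(cores, is.null, TRUE)
    mem <- mem[keep]; cores <- cores[keep]
    if (!length(mem)) next
    starts <- vapply(seq_along(mem), function(k)
      placed[mem[k]] + cores[[k]][1] - 1L, 0L)
    ends <- vapply(seq_along(mem), function(k)
      placed[mem[k]] + cores[[k]][2], 0L)
    origin <- min(starts)
    L <- max(ends) - origin
    counts <- matrix(0L, 4L, L)
    rownames(counts) <- c("A", "C", "G", "T")
    mem_ord <- mem[order(-lens[mem], ids[mem])]
    frag_cols <- list()
    for (f in mem_ord) {
      k <- match(f, mem)
      c1 <- cores[[k]][1]; c2 <- cores[[k]][2]
      colr <- (placed[f] + c1 - 1L - origin + 1L):(placed[f] + c2 - origin)
      bs <- chars(substr(frags[[f]], c1, c2))
      ok <- bs %in% rownames(counts)
      idx <- cbind(match(bs[ok], rownames(counts)), colr[ok])
      for (rr in seq_len(nrow(idx)))
        counts[idx[rr, 1], idx[rr, 2]] <- counts[idx[rr, 1], idx[rr, 2]] + 1L
      frag_cols[[as.character(f)]] <- list(cols = colr, bases = bs)
    }
    support <- colSums(counts)
    use <- which(support > 0L)
    ## a sharp support cliff at a terminus (junk protruding past a
    ## well-supported end) is an artifact: trim the support-1 run
    if (length(use) > 2L && max(support[use]) >= 3L) {
      r1 <- 0L
      while (r1 < length(use) - 1L && support[use[r1 + 1L]] == 1L) r1 <- r1 + 1L
      if (r1 > 0L && support[use[r1 + 1L]] >= 2L) use <- use[-seq_len(r1)]
      nu <- length(use)
      r2 <- 0L
      while (r2 < nu - 1L && support[use[nu - r2]] == 1L) r2 <- r2 + 1L
      if (r2 > 0L && support[use[nu - r2]] >= 2L)
        use <- use[-((nu - r2 + 1L):nu)]
    }
    cons <- character(L)
    maxc <- apply(counts, 2, max)
    conflicts <- integer(0)
    for (col in use) {
      tied <- rownames(counts)[counts[, col] == maxc[col]]
      if (length(tied) == 1L) cons[col] <- tied
      else {
        ## tie-break: base of the longest supporting fragment, then
        ## lexicographic
        pick <- ""
        for (f in as.character(mem_ord)) {
          fc <- frag_cols[[f]]
          hit <- which(fc$cols == col)
          if (length(hit) && fc$bases[hit] %in% tied) { pick <- fc$bases[hit]; break }
        }
        cons[col] <- if (nzchar(pick)) pick else sort(tied)[1]
      }
      if (sum(counts[, col] > 0L) > 1L) conflicts <- c(conflicts, col)
    }
    seqstr <- paste(cons[use], collapse = "")
    out[[length(out) + 1L]] <- structure(list(
      seq = seqstr, support = support[use], conflicts = conflicts,
      members = ids[mem], excluded = ids[which(excluded)]),
      class = "mm_transcript")
  }
  ord <- order(-vapply(out, function(t) nchar(t$seq), 0L),
               vapply(out, `[[`, "", "seq"))
  out[ord]
}

#' Reconstruct mature transcripts from a fragment pool
#'
#' Poly-A tails are trimmed before overlap computation; overlaps, layout and
#' consensus follow [find_overlaps()] and [layout_consensus()].
#'
#' @param fragments Named character vector of fragment sequences.
#' @param min_overlap,min_identity,max_end_skip See [overlap_align()].
#' @param min_members Minimum fragments per reported layout (stub filter).
#' @return Named list (`t01`, `t02`, ...) of `mm_transcript` objects.
#' @export
reconstruct_transcripts <- function(fragments, min_overlap = 20L,
                                    min_identity = 0.98, max_end_skip = 60L,
                                    min_members = 2L) {
  trimmed <- lapply(fragments, trim_polya)
  seqs <- vapply(trimmed, `[[`, "", "seq")
  seqs <- seqs[nchar(seqs) >= min_overlap]
  ovs <- find_overlaps(seqs, min_overlap, min_identity, max_end_skip)
  tr <- layout_consensus(seqs, ovs)
  ## drop weakly supported stubs and transcripts contained in longer ones
  tr <- Filter(function(t) length(t$members) >= min_members, tr)
  sq <- vapply(tr, `[[`, "", "seq")
  keep <- vapply(seq_along(sq), function(i) {
    !any(nchar(sq[-i]) > nchar(sq[i]) &
           vapply(sq[-i], function(x) grepl(sq[i], x, fixed = TRUE), TRUE))
  }, TRUE)
  tr <- tr[keep]
  names(tr) <- sprintf("t%02d", seq_along(tr))
  tr
}

#' Iteratively extend a partial transcript with overlapping fragments
#'
#' Mirrors the recovery of missing terminal modules: fragments overlapping a
#' transcript end contribute their protruding sequence; extension repeats to
#' a fixed point (or `rounds_max`), and is monotone non-decreasing in length.
#' When several fragments extend an end, their majority consensus is used.
#'
#' @param seed_transcript Character sequence.
#' @param fragment_pool Named character vector.
#' @param rounds_max Maximum extension rounds.
#' @param min_overlap,min_identity,max_end_skip See [overlap_align()].
#' @return The extended transcript sequence.
#' @export
iterative_extend <- function(seed_transcript, fragment_pool, rounds_max = 10L,
                             min_overlap = 20L, min_identity = 0.98,
                             max_end_skip = 60L) {
  cur <- seed_transcript
  round <- 0L
  while (round < rounds_max) {
    round <- round + 1L
    ext3 <- character(0); ext5 <- character(0)
    for (nm in names(fragment_pool)) {
      f <- trim_polya(fragment_pool[[nm]])$seq
      if (nchar(f) < min_overlap) next
      ov <- overlap_align(cur, f, min_overlap, min_identity, max_end_skip,
                          names_ab = c("seed", nm))
      if (is.null(ov)) next
      en <- ov$ends
      if (en["ra"] <= 2L && en["rb"] > 0L && en["lb"] <= max_end_skip)
        ext3 <- c(ext3, substr(f, ov$b_end + 1L, nchar(f)))
      if (en["la"] <= 2L && en["lb"] > 0L && en["rb"] <= max_end_skip)
        ext5 <- c(ext5, substr(f, 1L, ov$b_start - 1L))
    }
    consensus_ext <- function(xs, from_right) {
      if (!length(xs)) return("")
      L <- max(nchar(xs))
      cols <- character(0)
      for (i in seq_len(L)) {
        b <- vapply(xs, function(x) {
          n <- nchar(x)
          if (i > n) return(NA_character_)
          if (from_right) substr(x, i, i) else substr(x, n - i + 1L, n - i + 1L)
        }, "")
        b <- b[!is.na(b)]
        ## extend only while a majority of extending fragments agree to
        ## continue (lone protrusions are unprocessed-flank junk)
        if (length(b) * 2L < length(xs)) break
        cols <- c(cols, names(sort(table(b), decreasing = TRUE))[1])
      }
      if (from_right) paste(cols, collapse = "")
      else paste(rev(cols), collapse = "")
    }
    new <- paste0(consensus_ext(ext5, from_right = FALSE), cur,
                  consensus_ext(ext3, from_right = TRUE))
    if (identical(new, cur)) break
    cur <- new
  }
  cur
}
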