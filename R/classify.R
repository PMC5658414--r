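## Chromosome classification by recurrent cassette-flanking motifs, cassette
## delimitation, architecture summary and chimera splitting.

## group annotated modules into per-contig arrays (multi-module cassettes:
## modules spaced by ~100 bp of non-coding sequence; nested modules overlap)
module_arrays <- function(modules, max_gap = 400L) {
  out <- list()
  for (cid in unique(modules$contig_id)) {
    m <- modules[modules$contig_id == cid, , drop = FALSE]
    m <- m[order(m$start), , drop = FALSE]
    grp <- cumsum(c(1L, as.integer(m$start[-1L] >
                                     cummax(m$end)[-nrow(m)] + max_gap)))
    for (g in unique(grp)) {
      mm <- m[grp == g, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        contig_id = cid, array = g, astart = min(mm$start),
        aend = max(mm$end), n_modules = nrow(mm))
    }
  }
  do.call(rbind, out)
}

## wrap-aware window before/after an interval on the plus strand
flank_window <- function(ctg, pos, side, len) {
  L <- nchar(ctg$seq)
  len <- min(len, L - 1L)
  if (side == "up") {
    s <- (pos - len) %% L
    extract_interval(ctg, interval(ctg$id, s, s + len, "+"))
  } else {
    s <- pos %% L
    extract_interval(ctg, interval(ctg$id, s, s + len, "+"))
  }
}

## maximal shared high-identity block between two windows (anchored on a
## shared k-mer diagonal; best-scoring segment keeps identity above the
## threshold by construction of the mismatch penalty)
shared_block <- function(wa, wb, min_len = 100L, min_identity = 0.90,
                         k = 24L) {
  d <- anchor_diagonal(wa, wb, k)
  if (is.null(d)) return(NULL)
  va <- chars(wa); vb <- chars(wb)
  ## overlap of the two sequences on diagonal d (a_pos - b_pos = d)
  a1 <- max(1L, 1L + d); a2 <- min(length(va), length(vb) + d)
  if (a2 - a1 + 1L < min_len) return(NULL)
  m <- va[a1:a2] == vb[(a1 - d):(a2 - d)]
  pen <- min_identity / (1 - min_identity)
  sc <- ifelse(m, 1, -pen)
  ## maximal-sum segment, vectorized: best cumsum gain over a prefix minimum
  cs <- cumsum(sc)
  pre <- cummin(c(0, cs[-length(cs)]))
  gain <- cs - pre
  be <- which.max(gain)
  if (gain[be] <= 0) return(NULL)
  bs <- which(c(0, cs)[seq_len(be)] == pre[be])[1]
  len <- be - bs + 1L
  ident <- mean(m[bs:be])
  if (len <= min_len || ident <= min_identity) return(NULL)
  list(len = len, identity = ident,
       a_range = c(a1 + bs - 1L, a1 + be - 1L),
       b_range = c(a1 - d + bs - 1L, a1 - d + be - 1L))
}

#' Recurrent cassette-flanking motifs
#'
#' For each module array the sequence windows 5' and 3' of the array are
#' compared across contigs; maximal shared blocks of more than `min_len` bp
#' at more than `min_identity` identity define flanking motifs, grouped by
#' shared-block connectivity.  Motif support is the set of contigs sharing
#' the block; among competing motifs the most widely shared group wins by
#' construction.
#'
#' @param contigs Named list of [contig()] objects.
#' @param modules `mm_modules` table of annotated modules.
#' @param min_len Motif length threshold (bp; the motif must exceed it).
#' @param min_identity Identity threshold (exceeded, not met).
#' @param window Search window adjacent to the array (bp).
#' @return list(motifs = data.frame(motif_id, side, support, consensus),
#'   arrays = array table with `up_motif`/`down_motif` group ids).
#' @export
find_recurrent_flanks <- function(contigs, modules, min_len = 100L,
                                  min_identity = 0.90, window = 2000L) {
  arr <- module_arrays(modules)
  if (is.null(arr) || !nrow(arr)) {
    return(list(motifs = data.frame(), arrays = arr))
  }
  n <- nrow(arr)
  win <- list(up = character(n), down = character(n))
  for (i in seq_len(n)) {
    ctg <- contigs[[arr$contig_id[i]]]
    win$up[i] <- flank_window(ctg, arr$astart[i], "up", window)
    win$down[i] <- flank_window(ctg, arr$aend[i], "down", window)
  }
  arr$up_motif <- NA_integer_; arr$down_motif <- NA_integer_
  motif_rows <- list()
  gid <- 0L
  for (side in c("up", "down")) {
    ws <- win[[side]]
    ## representative-based clustering: each window joins the first
    ## established cluster whose representative shares a qualifying block
    reps <- integer(0)       # representative window index per cluster
    grp <- rep(NA_integer_, n)
    block_seq <- character(0)
    for (i in seq_len(n)) {
      joined <- FALSE
      for (ci in seq_along(reps)) {
        if (arr$contig_id[i] == arr$contig_id[reps[ci]]) next
        b <- shared_block(ws[i], ws[reps[ci]], min_len, min_identity)
        if (!is.null(b)) {
          grp[i] <- ci
          if (!nzchar(block_seq[ci]))
            block_seq[ci] <- substr(ws[i], b$a_range[1], b$a_range[2])
          joined <- TRUE
          break
        }
      }
      if (!joined) {
        reps <- c(reps, i)
        grp[i] <- length(reps)
        block_seq <- c(block_seq, "")
      }
    }
    for (ci in seq_along(reps)) {
      mem <- which(grp == ci)
      if (length(mem) < 2L) { grp[mem] <- NA_integer_; next }
      gid <- gid + 1L
      if (side == "up") arr$up_motif[mem] <- gid else arr$down_motif[mem] <- gid
      cons <- if (nzchar(block_seq[ci])) block_seq[ci] else ws[mem[1]]
      motif_rows[[length(motif_rows) + 1L]] <- data.frame(
        motif_id = gid, side = if (side == "up") "upstream" else "downstream",
        support = length(mem),
        members = paste(sort(unique(arr$contig_id[mem])), collapse = ","),
        consensus = cons)
    }
  }
  list(motifs = if (length(motif_rows)) do.call(rbind, motif_rows)
       else data.frame(),
       arrays = arr)
}

#' Group module-bearing contigs into chromosome classes
#'
#' Contigs sharing the same pair (or pairs, for bi-cassette chromosomes) of
#' cassette-flanking motifs form a class; contigs without any shared
#' module-adjacent motif pair are unclassified (`"U"`).  A contig combining
#' the upstream motif of one class with the downstream motif of another is
#' flagged as a hybrid chromosome.  Class labels A, B, C, ... are assigned
#' by descending member count.
#'
#' @param contigs Named list of [contig()] objects.
#' @param flanks Result of [find_recurrent_flanks()].
#' @return list(classes = data.frame(contig_id, class, hybrid),
#'   class_keys).
#' @export
group_into_classes <- function(contigs, flanks) {
  arr <- flanks$arrays
  if (is.null(arr) || !nrow(arr))
    return(list(classes = data.frame(contig_id = character(),
                                     class = character(), hybrid = logical()),
                class_keys = character()))
  cids <- unique(arr$contig_id)
  keys <- vapply(cids, function(cid) {
    a <- arr[arr$contig_id == cid, , drop = FALSE]
    pk <- paste0(a$up_motif, "/", a$down_motif)
    paste(sort(pk), collapse = ";")
  }, "")
  has_motif <- vapply(cids, function(cid) {
    a <- arr[arr$contig_id == cid, , drop = FALSE]
    any(!is.na(a$up_motif) & !is.na(a$down_motif))
  }, TRUE)
  tabk <- table(keys[has_motif])
  class_keys <- names(tabk)[tabk >= 2L]
  ## order classes by member count (desc), then key
  class_keys <- class_keys[order(-tabk[class_keys], class_keys)]
  lab <- setNames(LETTERS[seq_along(class_keys)], class_keys)
  cls <- character(length(cids)); hyb <- logical(length(cids))
  up_used <- lapply(class_keys, function(k)
    unlist(lapply(strsplit(k, ";")[[1]], function(p) strsplit(p, "/")[[1]][1])))
  down_used <- lapply(class_keys, function(k)
    unlist(lapply(strsplit(k, ";")[[1]], function(p) strsplit(p, "/")[[1]][2])))
  for (i in seq_along(cids)) {
    if (has_motif[i] && keys[i] %in% class_keys) {
      cls[i] <- lab[[keys[i]]]
    } else {
      cls[i] <- "U"
      a <- arr[arr$contig_id == cids[i], , drop = FALSE]
      u <- as.character(a$up_motif[!is.na(a$up_motif)])
      d <- as.character(a$down_motif[!is.na(a$down_motif)])
      if (length(u) && length(d)) {
        ku <- which(vapply(up_used, function(x) any(u %in% x), TRUE))
        kd <- which(vapply(down_used, function(x) any(d %in% x), TRUE))
        if (length(ku) && length(kd) && !length(intersect(ku, kd)))
          hyb[i] <- TRUE
      }
    }
  }
  list(classes = data.frame(contig_id = cids, class = cls, hybrid = hyb,
                            stringsAsFactors = FALSE),
       class_keys = class_keys)
}

## anchored per-base match profile of `m` against `cen` (center-star leg)
match_profile <- function(m, cen, k = 32L) {
  vm <- chars(m); vc <- chars(cen)
  km <- seq_kmers(m, k); kc <- seq_kmers(cen, k)
  keep <- !low_complexity(km)
  hit <- match(km, kc)
  ia <- which(!is.na(hit) & keep)
  prof <- rep(FALSE, length(vm))
  if (!length(ia)) return(list(prof = prof, anchored = 0))
  d <- ia - hit[ia]
  anchored <- 0L
  for (dd in unique(d)) {
    sel <- ia[d == dd]
    if (length(sel) < 5L) next
    ## extend the diagonal beyond its anchors (a substitution within k of a
    ## sequence end leaves the tail unanchored); out-of-register stretches
    ## only add chance-level matches that stay below the identity threshold
    a1 <- max(1L, 1L + dd)
    a2 <- min(length(vm), length(vc) + dd)
    b1 <- a1 - dd; b2 <- a2 - dd
    eq <- vm[a1:a2] == vc[b1:b2]
    prof[a1:a2] <- prof[a1:a2] | eq
    anchored <- anchored + (max(sel) + k - min(sel))
  }
  list(prof = prof, anchored = anchored)
}

#' Delimit cassettes on the members of a chromosome class
#'
#' Each member is aligned to a center member (pairwise anchor chains); the
#' per-column identity profile, smoothed with a trailing `window`-bp mean,
#' drops below `threshold` across the member-specific cassette; each
#' maximal low-identity run is reported as one cassette.
#'
#' @param contigs Named list of [contig()] objects.
#' @param members Contig ids of one class (>= 2).
#' @param window Smoothing window (bp).
#' @param threshold Identity threshold.
#' @return list(cassettes = data.frame(contig_id, start, end),
#'   unsegmented = character vector of members too divergent to anchor).
#' @export
delimit_cassettes <- function(contigs, members, window = 100L,
                              threshold = 0.90) {
  stopifnot(length(members) >= 2L)
  members <- sort(members)
  center <- members[1]
  cass <- list(); unseg <- character(0)
  for (m in members) {
    partner <- if (m == center) members[2] else center
    mp <- match_profile(contigs[[m]]$seq, contigs[[partner]]$seq)
    if (mp$anchored < 0.3 * nchar(contigs[[m]]$seq)) {
      unseg <- c(unseg, m)
      next
    }
    x <- as.numeric(mp$prof)
    cs <- cumsum(x)
    L <- length(x)
    if (L < window) { unseg <- c(unseg, m); next }
    idx <- window:L
    wm <- (cs[idx] - c(0, cs)[idx - window + 1L]) / window
    below <- wm < threshold
    r <- rle(below)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (q in which(r$values)) {
      ## trailing-window positions: column i of wm is base window+i-1; the
      ## low-identity region starts about one window before the first
      ## crossing
      b1 <- max(0L, starts[q] - 1L)            # 0-based
      b2 <- min(L, ends[q] + window - 1L)
      ## refine to the unmatched run inside the candidate span
      seg <- which(!mp$prof)
      seg <- seg[seg > b1 & seg <= b2]
      if (!length(seg)) next
      if (max(seg) - min(seg) + 1L < window / 2) next
      cass[[length(cass) + 1L]] <- data.frame(
        contig_id = m, start = min(seg) - 1L, end = max(seg))
    }
  }
  out <- if (length(cass)) do.call(rbind, cass) else
    data.frame(contig_id = character(), start = integer(), end = integer())
  ## merge near-adjacent runs on the same contig
  merged <- list()
  for (cid in unique(out$contig_id)) {
    o <- out[out$contig_id == cid, , drop = FALSE]
    o <- o[order(o$start), , drop = FALSE]
    cur <- o[1, ]
    for (i in seq_len(nrow(o))[-1]) {
      if (o$start[i] <= cur$end + 30L) cur$end <- max(cur$end, o$end[i])
      else { merged[[length(merged) + 1L]] <- cur; cur <- o[i, ] }
    }
    merged[[length(merged) + 1L]] <- cur
  }
  out <- if (length(merged)) do.call(rbind, merged) else out
  rownames(out) <- NULL
  list(cassettes = out, unsegmented = unseg)
}

#' Architecture summary (chromosome categories and totals)
#'
#' Per contig: class label (or `"U"`), cassette count and modules per
#' cassette; dataset totals count mono-module, multi-module and
#' multi-cassette chromosomes and the total module count.
#'
#' @param classes data.frame(contig_id, class) from [group_into_classes()]
#'   (or truth).
#' @param cassettes data.frame(contig_id, start, end).
#' @param modules `mm_modules` table.
#' @return list(per_contig, totals).
#' @export
summarize_architecture <- function(classes, cassettes, modules) {
  rows <- list()
  for (i in seq_len(nrow(classes))) {
    cid <- classes$contig_id[i]
    cs <- cassettes[cassettes$contig_id == cid, , drop = FALSE]
    m <- modules[modules$contig_id == cid, , drop = FALSE]
    mods_per_cas <- if (nrow(cs)) vapply(seq_len(nrow(cs)), function(q)
      sum(m$start >= cs$start[q] & m$end <= cs$end[q]), 0L) else integer(0)
    category <- if (nrow(cs) >= 2L && sum(mods_per_cas > 0L) >= 2L) "multi-cassette"
    else if (any(mods_per_cas >= 2L) || nrow(m) >= 2L) "multi-module"
    else "mono-module"
    rows[[i]] <- data.frame(contig_id = cid, class = classes$class[i],
                            n_cassettes = nrow(cs), n_modules = nrow(m),
                            category = category)
  }
  per_contig <- do.call(rbind, rows)
  totals <- list(
    n_chromosomes = nrow(per_contig),
    n_modules = nrow(modules),
    mono_module = sum(per_contig$category == "mono-module"),
    multi_module = sum(per_contig$category == "multi-module"),
    multi_cassette = sum(per_contig$category == "multi-cassette"),
    unclassified = sum(per_contig$class == "U"),
    classes = {
      tab <- table(per_contig$class[per_contig$class != "U"])
      setNames(as.integer(tab), names(tab))
    })
  list(per_contig = per_contig, totals = totals)
}

#' Split a chimeric contig by its coverage step
#'
#' Mitochondrial contigs show high read coverage; a chimeric
#' mito/nuclear assembly shows a sharp coverage step.  The contig is cut at
#' the maximal step between a high-coverage (`>= high_floor`) and a
#' low-coverage (`< low_ceiling`) segment; parts are labelled
#' mito-candidate / non-mito.
#'
#' @param ctg An [contig()] with per-base coverage.
#' @param high_floor Minimum mean coverage of the mitochondrial moiety.
#' @param low_ceiling Maximum mean coverage of the non-mito moiety.
#' @param min_seg Minimum segment length considered (bp).
#' @return list of parts: each list(contig, label, range); a single
#'   "mito-candidate"/"unsplit" part when no qualifying step exists.
#' @export
split_chimeric <- function(ctg, high_floor = 200, low_ceiling = 100,
                           min_seg = 200L) {
  cov <- ctg$coverage
  if (is.null(cov)) {
    warning("no coverage available for ", ctg$id, "; contig left unsplit")
    return(list(list(contig = ctg, label = "unsplit",
                     range = c(0L, nchar(ctg$seq)))))
  }
  L <- length(cov)
  if (L < 2L * min_seg)
    return(list(list(contig = ctg, label = "unsplit", range = c(0L, L))))
  cs <- cumsum(cov)
  cuts <- min_seg:(L - min_seg)
  meanL <- cs[cuts] / cuts
  meanR <- (cs[L] - cs[cuts]) / (L - cuts)
  d <- abs(meanL - meanR)
  best <- cuts[which.max(d)]
  ml <- cs[best] / best; mr <- (cs[L] - cs[best]) / (L - best)
  hi <- max(ml, mr); lo <- min(ml, mr)
  if (hi < high_floor || lo >= low_ceiling)
    return(list(list(contig = ctg, label = "unsplit", range = c(0L, L))))
  part <- function(a, b) contig(paste0(ctg$id, "_", a, "_", b),
                                substr(ctg$seq, a + 1L, b), circular = FALSE,
                                coverage = cov[(a + 1L):b])
  lab <- function(m) if (m >= high_floor) "mito-candidate" else "non-mito"
  list(list(contig = part(0L, best), label = lab(ml), range = c(0L, best)),
       list(contig = part(best, L), label = lab(mr), range = c(best, L)))
}

#' Full chromosome classification stage
#'
#' Motif discovery, class grouping, cassette delimitation and architecture
#' summary in one call.
#'
#' @param contigs Named list of [contig()] objects.
#' @param modules `mm_modules` table.
#' @param min_len,min_identity Motif thresholds.
#' @param window Cassette smoothing window.
#' @return list(flanks, classes, cassettes, summary).
#' @export
classify_chromosomes <- function(contigs, modules, min_len = 100L,
                                 min_identity = 0.90, window = 100L) {
  fl <- find_recurrent_flanks(contigs, modules, min_len, min_identity)
  gr <- group_into_classes(contigs, fl)
  cass <- list(); unseg <- character(0)
  for (cl in setdiff(unique(gr$classes$class), "U")) {
    mem <- gr$classes$contig_id[gr$classes$class == cl]
    dc <- delimit_cassettes(contigs, mem, window = window)
    if (nrow(dc$cassettes)) cass[[cl]] <- dc$cassettes
    unseg <- c(unseg, dc$unsegmented)
  }
  cassettes <- if (length(cass)) do.call(rbind, cass) else
    data.frame(contig_id = character(), start = integer(), end = integer())
  rownames(cassettes) <- NULL
  summary <- summarize_architecture(gr$classes, cassettes, modules)
  list(flanks = fl, classes = gr$classes, cassettes = cassettes,
       summary = summary, unsegmented = unseg)
}
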