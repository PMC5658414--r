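## Map mature transcripts onto genomic contigs, delimit modules, resolve
## trans-splicing junctions, detect nested/overlapping dual-purpose modules
## and classify trans-splicing errors.

low_complexity <- function(x)
  grepl("^(.)\\1+$", x, perl = TRUE) | grepl("^(..)\\1+.?$", x, perl = TRUE)

## strand-sequence cache: transcript-sense genomic sequence per strand
strand_seqs <- function(contigs) {
  out <- list()
  for (id in names(contigs)) {
    s <- contigs[[id]]$seq
    out[[id]] <- list("+" = chars(s), "-" = chars(reverse_complement(s)))
  }
  out
}

#' Locate maximal local alignments of transcripts on genomic contigs
#'
#' Seed-and-extend mapping (exact k-mer seeds, x-drop extension) with
#' editing-aware scoring: a genomic A may pair with transcript G (A-to-I)
#' and a genomic C with transcript U (C-to-U); other mismatches are
#' penalized.  Hit ends are trimmed back to strict matches.
#'
#' @param transcripts Named character vector of mature transcript sequences.
#' @param contigs Named list of [contig()] objects.
#' @param min_len Minimum hit length (nt).
#' @param min_identity Minimum identity (editing-aware matches count).
#' @param k,step Seed size and spacing.
#' @return data.frame of hits: `transcript`, `tstart`, `tend` (0-based
#'   half-open on the transcript), `contig_id`, `gstart`, `gend` (contig
#'   coordinates), `strand`, `sstart` (strand-sequence coordinate),
#'   `identity`, `aware` (count of editing-tolerated columns).
#' @export
local_align_transcript <- function(transcripts, contigs, min_len = 30L,
                                   min_identity = 0.9, k = 20L, step = 8L) {
  sseqs <- strand_seqs(contigs)
  tch <- lapply(transcripts, chars)
  subjects <- lapply(names(contigs), function(cid) {
    s <- contigs[[cid]]$seq
    list(id = cid, "+" = s, "-" = reverse_complement(s))
  })
  seed_table <- function(seqs, kk, st) {
    rows <- list()
    for (tn in names(seqs)) {
      L <- nchar(seqs[[tn]])
      if (L < kk) next
      stp <- unique(c(seq(1L, L - kk + 1L, by = st), L - kk + 1L))
      sq <- substring(seqs[[tn]], stp, stp + kk - 1L)
      keep <- !low_complexity(sq)
      if (!any(keep)) next
      rows[[tn]] <- data.frame(transcript = tn, tpos = stp[keep] - 1L,
                               seed = sq[keep])
    }
    if (!length(rows)) return(NULL)
    do.call(rbind, rows)
  }
  match_seeds <- function(seeds, subj_field) {
    useq <- unique(seeds$seed)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(useq))
    hit_rows <- list()
    for (sb in subjects) {
      for (strand in c("+", "-")) {
        subject <- Biostrings::DNAString(subj_field(sb[[strand]]))
        m <- Biostrings::matchPDict(pd, subject)
        cnt <- S4Vectors::elementNROWS(m)
        for (ui in which(cnt > 0L)) {
          starts <- IRanges::start(m[[ui]]) - 1L
          for (r in which(seeds$seed == useq[ui])) {
            hit_rows[[length(hit_rows) + 1L]] <- data.frame(
              transcript = seeds$transcript[r], tpos = seeds$tpos[r],
              contig_id = sb$id, strand = strand, gpos = starts)
          }
        }
      }
    }
    if (!length(hit_rows)) return(NULL)
    do.call(rbind, hit_rows)
  }
  extend_all <- function(sm) {
    out <- list()
    sm$diag <- sm$gpos - sm$tpos
    key <- paste(sm$transcript, sm$contig_id, sm$strand, sm$diag)
    for (grp in split(sm, key)) {
      tn <- grp$transcript[1]; cid <- grp$contig_id[1]; strand <- grp$strand[1]
      diag <- grp$diag[1]
      tv <- tch[[tn]]; gv <- sseqs[[cid]][[strand]]
      a0 <- min(grp$tpos); a1 <- max(grp$tpos) + k - 1L
      ext <- xdrop_extend(tv, gv, diag, a0, a1)
      if (is.null(ext)) next
      len <- ext[2] - ext[1] + 1L
      if (len < min_len) next
      seg_t <- tv[(ext[1] + 1L):(ext[2] + 1L)]
      seg_g <- gv[(ext[1] + diag + 1L):(ext[2] + diag + 1L)]
      am <- edit_aware_match(seg_g, seg_t)
      ident <- mean(am)
      if (ident < min_identity) next
      ## a hit dominated by one homopolymer (a chance match of a U tract)
      ## is not a module
      if (len - max(rle(seg_t)$lengths) < 15L) next
      ## editing-aware matching must not carry the hit: even a heavily
      ## edited module keeps most bases genome-identical, while pyrimidine-
      ## rich junk "matching" a U tract does not
      if (mean(seg_g == seg_t) < 0.75) next
      L <- length(gv)
      ss <- ext[1] + diag; se <- ext[2] + diag + 1L
      if (strand == "+") { g1 <- ss; g2 <- se } else { g1 <- L - se; g2 <- L - ss }
      out[[length(out) + 1L]] <- data.frame(
        transcript = tn, tstart = ext[1], tend = ext[2] + 1L,
        contig_id = cid, gstart = g1, gend = g2, strand = strand,
        sstart = ss, identity = ident, aware = sum(am & seg_g != seg_t))
    }
    if (!length(out)) return(NULL)
    do.call(rbind, out)
  }
  seeds <- seed_table(transcripts, k, step)
  if (is.null(seeds)) return(empty_hits())
  sm <- match_seeds(seeds, identity)
  hits <- if (!is.null(sm)) extend_all(sm) else NULL
  ## rescue pass for regions whose exact seeds are all broken by dense
  ## editing: deamination-collapsed alphabet (A-to-I folds G onto A,
  ## C-to-U folds T onto C) for seeding only; extension and identity are
  ## still computed on the real sequences
  collapse <- function(x) chartr("GT", "AC", x)
  gap_seqs <- list()
  for (tn in names(transcripts)) {
    L <- nchar(transcripts[[tn]])
    cov <- rep(FALSE, L)
    if (!is.null(hits)) {
      h <- hits[hits$transcript == tn, , drop = FALSE]
      for (r in seq_len(nrow(h))) cov[(h$tstart[r] + 1L):h$tend[r]] <- TRUE
    }
    r <- rle(!cov)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    gi <- 0L
    for (q in which(r$values & r$lengths >= 25L)) {
      gi <- gi + 1L
      a <- max(1L, starts[q] - 5L); b <- min(L, ends[q] + 5L)
      gap_seqs[[paste0(tn, "\r", a - 1L)]] <- substr(transcripts[[tn]], a, b)
    }
  }
  if (length(gap_seqs)) {
    gseeds <- seed_table(lapply(gap_seqs, collapse), k, 4L)
    if (!is.null(gseeds)) {
      sm2 <- match_seeds(gseeds, collapse)
      if (!is.null(sm2)) {
        ## map gap-local coordinates back to the transcript
        parts <- strsplit(sm2$transcript, "\r", fixed = TRUE)
        sm2$transcript <- vapply(parts, `[[`, "", 1)
        sm2$tpos <- sm2$tpos + as.integer(vapply(parts, `[[`, "", 2))
        h2 <- extend_all(sm2)
        hits <- rbind(hits, h2)
      }
    }
  }
  if (is.null(hits)) return(empty_hits())
  ## absorb duplicate/contained hits on the same placement
  hits <- hits[order(hits$transcript, hits$tstart, -(hits$tend)), ]
  keep <- !duplicated(hits[, c("transcript", "tstart", "tend", "contig_id",
                               "strand", "sstart")])
  hits <- hits[keep, ]
  rownames(hits) <- NULL
  hits
}

empty_hits <- function() data.frame(
  transcript = character(), tstart = integer(), tend = integer(),
  contig_id = character(), gstart = integer(), gend = integer(),
  strand = character(), sstart = integer(), identity = numeric(),
  aware = integer())

## x-drop extension along a fixed diagonal; returns 0-based inclusive
## transcript range trimmed to strict end matches, or NULL
xdrop_extend <- function(tv, gv, diag, a0, a1, xdrop = 10L) {
  nt <- length(tv); ng <- length(gv)
  score_step <- function(i) {
    g <- gv[i + diag + 1L]; t <- tv[i + 1L]
    if (is.na(g) || is.na(t)) return(NA_real_)
    if (g == t) 1 else if ((g == "A" && t == "G") || (g == "C" && t == "T")) 1
    else -3
  }
  ## right extension
  best <- 0; cur <- 0; e <- a1
  i <- a1 + 1L
  while (i < nt && i + diag < ng) {
    st <- score_step(i)
    if (is.na(st)) break
    cur <- cur + st
    if (cur > best) { best <- cur; e <- i }
    if (cur < best - xdrop) break
    i <- i + 1L
  }
  ## left extension
  best <- 0; cur <- 0; s <- a0
  i <- a0 - 1L
  while (i >= 0L && i + diag >= 0L) {
    st <- score_step(i)
    if (is.na(st)) break
    cur <- cur + st
    if (cur > best) { best <- cur; s <- i }
    if (cur < best - xdrop) break
    i <- i - 1L
  }
  ## trim ends to strict matches
  while (s <= e && gv[s + diag + 1L] != tv[s + 1L]) s <- s + 1L
  while (e >= s && gv[e + diag + 1L] != tv[e + 1L]) e <- e - 1L
  if (e < s) return(NULL)
  c(s, e)
}

## the junction convention, forward: starting at transcript position p with
## genomic continuation along `diag`, extend while the genome encodes the
## transcript exactly (upstream-maximal attribution)
convention_forward <- function(tv, gv, diag, p, limit = 70L) {
  e <- p; i <- p
  n <- min(length(tv), length(gv) - diag)
  while (i < n && i < p + limit) {
    g <- gv[i + diag + 1L]; t <- tv[i + 1L]
    if (is.na(g) || is.na(t) || g != t) break
    e <- i + 1L; i <- i + 1L
  }
  e
}

## the junction convention, backward: first position reachable from `anchor`
## by consecutive strict matches walking left (>= floor)
convention_backward <- function(tv, gv, diag, anchor, floor_pos) {
  s <- anchor
  while (s > floor_pos) {
    g <- gv[s + diag]; t <- tv[s]      # position s-1, 0-based
    if (is.na(g) || is.na(t) || g != t) break
    s <- s - 1L
  }
  s
}

#' Resolve the junction between two consecutive module hits
#'
#' Applies the junction convention: the upstream module is extended as far
#' as the genome encodes the transcript (upstream-maximal attribution); at
#' U-appendage junctions the boundary is placed downstream of the last
#' genome-encoded T, and trailing tract Us encoded at the start of the
#' downstream module's genomic copy are attributed to the genome as well.
#' Ambiguity beyond 6 nt of shared identity is flagged unresolved.
#'
#' @param up_hit,down_hit Single hit rows (see [local_align_transcript()]).
#' @param transcript Transcript sequence.
#' @param contigs Named list of [contig()] objects.
#' @return list(junction, tract_len, down_start, width, rule, ok, note).
#' @export
resolve_junction <- function(up_hit, down_hit, transcript, contigs) {
  sseqs <- strand_seqs(contigs)
  resolve_junction_impl(chars(transcript), up_hit, down_hit, sseqs)
}

## strict-match runs of a hit along its diagonal; 0-based positions
hit_strict_runs <- function(tv, gv, dg, h_start, h_end) {
  idx0 <- seq(h_start, h_end - 1L)
  sv <- gv[idx0 + dg + 1L] == tv[idx0 + 1L]
  r <- rle(sv)
  ends <- cumsum(r$lengths)
  data.frame(start = h_start + ends - r$lengths, end = h_start + ends,
             strict = r$values, len = r$lengths)
}

## canonical end of a module hit: the last long strict run belongs to the
## module (its final bases are exact by construction; chance strict runs in
## overshoot regions are short), extended forward while the genome keeps
## encoding the transcript
refine_hit_end <- function(tv, gv, dg, h_start, h_end, min_run = 14L) {
  runs <- hit_strict_runs(tv, gv, dg, h_start, h_end)
  good <- which(runs$strict & runs$len >= min_run)
  j0 <- if (length(good)) runs$end[max(good)] else max(h_start, h_end - min_run)
  convention_forward(tv, gv, dg, j0)
}

## canonical start of a downstream module hit: the first long strict run,
## extended backward (genome-encoded Ts ahead of the module absorb tract Us)
refine_hit_start <- function(tv, gv, dg, h_start, h_end, floor_pos,
                             min_run = 14L) {
  runs <- hit_strict_runs(tv, gv, dg, h_start, h_end)
  good <- which(runs$strict & runs$len >= min_run)
  s0 <- if (length(good)) runs$start[min(good)] else min(h_end - 1L, h_start + min_run)
  convention_backward(tv, gv, dg, s0, floor_pos)
}

resolve_junction_impl <- function(tv, up_hit, down_hit, sseqs) {
  gv_up <- sseqs[[up_hit$contig_id]][[up_hit$strand]]
  dg_up <- up_hit$sstart - up_hit$tstart
  junction <- refine_hit_end(tv, gv_up, dg_up, up_hit$tstart, up_hit$tend)
  gv_dn <- sseqs[[down_hit$contig_id]][[down_hit$strand]]
  dg_dn <- down_hit$sstart - down_hit$tstart
  s <- refine_hit_start(tv, gv_dn, dg_dn, down_hit$tstart, down_hit$tend,
                        junction)
  s <- max(s, junction)
  tract <- s - junction
  note <- ""
  ok <- TRUE
  if (tract > 0L) {
    gap_seq <- tv[(junction + 1L):s]
    if (!all(gap_seq == "T")) {
      ok <- FALSE
      note <- "uncovered gap not explained by a poly-U run"
      tract <- 0L
    }
  }
  ## ambiguity width: shared identical run measured at the downstream
  ## module start against its upstream genomic context
  w <- 0L
  i <- 1L
  while (i <= 10L && s - i >= 0L && s - i + dg_dn >= 0L) {
    if (gv_dn[s - i + dg_dn + 1L] != tv[s - i + 1L]) break
    w <- i; i <- i + 1L
  }
  rule <- if (!ok) "missing-module"
  else if (tract > 0L) "downstream-of-T"
  else if (w == 0L) "unique"
  else "upstream-maximal"
  if (w > 6L) { rule <- "unresolved"; }
  list(junction = junction, tract_len = tract, down_start = s, width = w,
       rule = rule, ok = ok, note = note)
}

#' Delimit modules of one transcript from its genomic hits
#'
#' Chains hits 5'->3' across the transcript, refines module boundaries and
#' junctions under the junction convention, accepts internal gaps only when
#' a poly-U run (U-appendage tract) explains them, and reports missing
#' modules otherwise.
#'
#' @param transcript_name Name of the transcript.
#' @param tseq Transcript sequence.
#' @param hits Hit data.frame from [local_align_transcript()] (all
#'   transcripts; filtered internally).
#' @param contigs Named list of [contig()] objects.
#' @param sseqs Optional precomputed [strand_seqs] cache (internal reuse).
#' @return list(modules, junctions, diagnostics).
#' @export
delimit_modules <- function(transcript_name, tseq, hits, contigs,
                            sseqs = NULL) {
  if (is.null(sseqs)) sseqs <- strand_seqs(contigs)
  tv <- chars(tseq)
  Tn <- length(tv)
  h <- hits[hits$transcript == transcript_name, , drop = FALSE]
  diagnostics <- list(); mrows <- list(); jrows <- list()
  if (!nrow(h)) {
    return(list(modules = NULL, junctions = NULL,
                diagnostics = data.frame(kind = "no-hits", tpos = 0L,
                                         note = "transcript maps nowhere")))
  }
  ## chain: greedy 5'->3' tiling
  h <- h[order(h$tstart, -h$tend), , drop = FALSE]
  chain <- integer(0)
  cur_end <- -1L
  repeat {
    cand <- which(h$tstart <= cur_end + 60L & h$tend > cur_end + 10L)
    cand <- setdiff(cand, chain)
    if (!length(cand) && cur_end < 0L) cand <- 1L
    if (!length(cand)) {
      nxt <- which(h$tstart > cur_end & !(seq_len(nrow(h)) %in% chain))
      if (!length(nxt)) break
      diagnostics[[length(diagnostics) + 1L]] <- data.frame(
        kind = "missing-module", tpos = cur_end,
        note = "gap before next mapped module")
      cand <- nxt[1]
    }
    pick <- cand[order(h$tstart[cand], -h$tend[cand])][1]
    chain <- c(chain, pick)
    cur_end <- h$tend[pick]
    if (cur_end >= Tn) break
  }
  ch <- h[chain, , drop = FALSE]
  n <- nrow(ch)
  starts <- integer(n); ends <- integer(n)
  starts[1] <- ch$tstart[1]
  if (starts[1] > 0L)
    diagnostics[[length(diagnostics) + 1L]] <- data.frame(
      kind = "missing-module", tpos = 0L,
      note = "transcript 5' end not covered")
  for (i in seq_len(n)) {
    gv <- sseqs[[ch$contig_id[i]]][[ch$strand[i]]]
    dg <- ch$sstart[i] - ch$tstart[i]
    if (i < n) {
      res <- resolve_junction_impl(tv, ch[i, ], ch[i + 1L, ], sseqs)
      ends[i] <- res$junction
      starts[i + 1L] <- res$down_start
      jrows[[length(jrows) + 1L]] <- data.frame(
        gene = transcript_name, after_ordinal = i, tpos = res$junction,
        tract_len = res$tract_len, width = res$width, rule = res$rule,
        terminal = FALSE)
      if (!res$ok)
        diagnostics[[length(diagnostics) + 1L]] <- data.frame(
          kind = "missing-module", tpos = res$junction, note = res$note)
    } else {
      e <- refine_hit_end(tv, gv, dg, ch$tstart[i], ch$tend[i])
      ends[i] <- e
      tail_len <- Tn - e
      tract <- 0L
      if (tail_len > 0L) {
        tail_seq <- tv[(e + 1L):Tn]
        if (all(tail_seq == "T")) tract <- tail_len
        else diagnostics[[length(diagnostics) + 1L]] <- data.frame(
          kind = "missing-module", tpos = e,
          note = "transcript 3' end not covered")
      }
      jrows[[length(jrows) + 1L]] <- data.frame(
        gene = transcript_name, after_ordinal = i, tpos = e,
        tract_len = tract, width = 0L,
        rule = if (tract > 0L) "downstream-of-T" else "genome-encoded-terminal",
        terminal = TRUE)
    }
    L <- length(gv)
    dgi <- ch$sstart[i] - ch$tstart[i]
    ss <- starts[i] + dgi; se <- ends[i] + dgi
    if (ch$strand[i] == "+") { g1 <- ss; g2 <- se } else { g1 <- L - se; g2 <- L - ss }
    mrows[[length(mrows) + 1L]] <- data.frame(
      gene = transcript_name, ordinal = i, contig_id = ch$contig_id[i],
      start = g1, end = g2, strand = ch$strand[i],
      frame_offset = starts[i] %% 3L, tstart = starts[i], tend = ends[i])
  }
  mods <- do.call(rbind, mrows)
  class(mods) <- c("mm_modules", "data.frame")
  list(modules = mods, junctions = do.call(rbind, jrows),
       diagnostics = if (length(diagnostics)) do.call(rbind, diagnostics)
       else NULL)
}

#' Annotate a set of transcripts against contigs
#'
#' Runs [local_align_transcript()] and [delimit_modules()] for every
#' transcript.
#'
#' @param transcripts Named character vector.
#' @param contigs Named list of [contig()] objects.
#' @param min_len,min_identity See [local_align_transcript()].
#' @return list(modules, junctions, diagnostics) across all transcripts.
#' @export
annotate_transcripts <- function(transcripts, contigs, min_len = 30L,
                                 min_identity = 0.9) {
  hits <- local_align_transcript(transcripts, contigs, min_len, min_identity)
  sseqs <- strand_seqs(contigs)
  mods <- list(); jns <- list(); dg <- list()
  for (tn in names(transcripts)) {
    r <- delimit_modules(tn, transcripts[[tn]], hits, contigs, sseqs = sseqs)
    if (!is.null(r$modules)) mods[[tn]] <- r$modules
    if (!is.null(r$junctions)) jns[[tn]] <- r$junctions
    if (!is.null(r$diagnostics)) dg[[tn]] <- cbind(transcript = tn, r$diagnostics)
  }
  out_mods <- if (length(mods)) do.call(rbind, mods) else NULL
  if (!is.null(out_mods)) {
    rownames(out_mods) <- NULL
    class(out_mods) <- c("mm_modules", "data.frame")
  }
  list(modules = out_mods,
       junctions = if (length(jns)) do.call(rbind, jns) else NULL,
       diagnostics = if (length(dg)) do.call(rbind, dg) else NULL,
       hits = hits)
}

module_phase <- function(mods, i, g) {
  if (mods$strand[i] == "+") (mods$frame_offset[i] + g - mods$start[i]) %% 3L
  else (mods$frame_offset[i] + (mods$end[i] - 1L - g)) %% 3L
}

#' Genomic overlaps between modules of different genes
#'
#' Reports every genomic overlap between annotated modules of different
#' gene/ordinal identity: strand relation, overlap in bp, and for
#' same-strand protein module pairs whether the reading frames coincide and
#' the overlap in amino acids (`floor(overlap_bp / 3)` when in frame).
#' Nested (dual-purpose) modules are flagged when one module lies entirely
#' inside the other.
#'
#' @param mods An `mm_modules` table (annotated or truth).
#' @return data.frame of overlap pairs.
#' @export
find_module_overlaps <- function(mods) {
  out <- list()
  if (nrow(mods) < 2L) return(empty_overlaps())
  for (i in seq_len(nrow(mods) - 1L)) {
    for (j in (i + 1L):nrow(mods)) {
      if (mods$contig_id[i] != mods$contig_id[j]) next
      if (mods$gene[i] == mods$gene[j] && mods$ordinal[i] == mods$ordinal[j]) next
      s <- max(mods$start[i], mods$start[j])
      e <- min(mods$end[i], mods$end[j])
      if (e <= s) next
      li <- mods$end[i] - mods$start[i]; lj <- mods$end[j] - mods$start[j]
      if (li >= lj) { enc <- i; emb <- j } else { enc <- j; emb <- i }
      nested <- mods$start[emb] >= mods$start[enc] && mods$end[emb] <= mods$end[enc]
      same <- mods$strand[i] == mods$strand[j]
      frames_equal <- NA
      overlap_aa <- NA_integer_
      if (same && !is.na(mods$frame_offset[i]) && !is.na(mods$frame_offset[j])) {
        frames_equal <- module_phase(mods, i, s) == module_phase(mods, j, s)
        if (isTRUE(frames_equal)) overlap_aa <- (e - s) %/% 3L
      }
      out[[length(out) + 1L]] <- data.frame(
        enclosing_gene = mods$gene[enc], enclosing_ordinal = mods$ordinal[enc],
        embedded_gene = mods$gene[emb], embedded_ordinal = mods$ordinal[emb],
        contig_id = mods$contig_id[i],
        strand_relation = if (same) "same" else "opposite",
        overlap_bp = e - s, overlap_aa = overlap_aa,
        frames_equal = frames_equal, nested = nested)
    }
  }
  if (!length(out)) return(empty_overlaps())
  do.call(rbind, out)
}

empty_overlaps <- function() data.frame(
  enclosing_gene = character(), enclosing_ordinal = integer(),
  embedded_gene = character(), embedded_ordinal = integer(),
  contig_id = character(), strand_relation = character(),
  overlap_bp = integer(), overlap_aa = integer(), frames_equal = logical(),
  nested = logical())

#' Classify a trans-splicing error in a fragment
#'
#' Compares a fragment against the expected mature transcripts and the
#' junction map and assigns one of the four error types: (i) over- or
#' under-trimming at a joining end; (ii) U addition at a junction that does
#' not normally undergo U-appendage; (iii) an incompletely trimmed 3' end in
#' place of a U tract; (iv) mis-joining of modules of non-cognate genes.
#' When several signatures co-occur the priority is iv > iii > ii > i.
#'
#' @param fragment Fragment sequence.
#' @param transcripts Named character vector of expected mature transcripts.
#' @param junction_map data.frame with `gene`, `tpos`, `tract_len`
#'   (non-terminal junctions).
#' @return One of `"i"`, `"ii"`, `"iii"`, `"iv"`, `"none"`.
#' @export
classify_junction_errors <- function(fragment, transcripts, junction_map) {
  frag <- trim_polya(fragment)$seq
  n <- nchar(frag)
  best <- NULL; best_score <- -Inf
  for (tn in names(transcripts)) {
    al <- olap_align_cpp(frag, transcripts[[tn]])
    if (al$score > best_score) { best_score <- al$score; best <- al; best$tn <- tn }
  }
  if (is.null(best)) return("none")
  covered <- best$a_end - best$a_start + 1L
  ident <- if (best$cols > 0) best$matches / best$cols else 0
  if (covered >= n - 2L && ident >= 0.995 && best$cols >= n - 2L &&
      sum(is.na(best$a_idx)) + sum(is.na(best$b_idx)) == 0L)
    return("none")
  ## type iv: the uncovered part of the fragment maps to a different gene
  un_left <- best$a_start - 1L; un_right <- n - best$a_end
  if (max(un_left, un_right) >= 30L) {
    rest <- if (un_right >= un_left) substr(frag, best$a_end + 1L, n)
    else substr(frag, 1L, best$a_start - 1L)
    for (tn in setdiff(names(transcripts), best$tn)) {
      al2 <- olap_align_cpp(rest, transcripts[[tn]])
      cov2 <- al2$a_end - al2$a_start + 1L
      id2 <- if (al2$cols > 0) al2$matches / al2$cols else 0
      if (cov2 >= min(30L, nchar(rest)) && id2 >= 0.95 &&
          cov2 >= 0.8 * nchar(rest))
        return("iv")
    }
  }
  ## inspect discrepancies of the best alignment near junctions
  jm <- junction_map[junction_map$gene == best$tn, , drop = FALSE]
  a_idx <- best$a_idx; b_idx <- best$b_idx
  ins_cols <- which(is.na(b_idx))   # fragment-only columns (insertions)
  del_cols <- which(is.na(a_idx))   # transcript-only columns (deletions)
  near <- function(tpos, cols) {
    if (!length(cols)) return(logical(0))
    bpos <- vapply(cols, function(cc) {
      prev <- b_idx[seq_len(cc)]
      prev <- prev[!is.na(prev)]
      if (length(prev)) prev[length(prev)] else 0L
    }, 0L)
    abs(bpos - tpos) <= 6L
  }
  mm_cols <- which(!is.na(a_idx) & !is.na(b_idx))
  frag_ch <- chars(frag); tr_ch <- chars(transcripts[[best$tn]])
  mismatch <- mm_cols[frag_ch[a_idx[mm_cols]] != tr_ch[b_idx[mm_cols]]]
  if (nrow(jm)) {
    ## iii: at a U-appendage junction, the tract region is not U
    tr_jn <- jm[jm$tract_len > 0L, , drop = FALSE]
    for (r in seq_len(nrow(tr_jn))) {
      tpos <- tr_jn$tpos[r]; tl <- tr_jn$tract_len[r]
      cols <- which(!is.na(b_idx) & b_idx > tpos & b_idx <= tpos + tl)
      if (!length(cols)) next
      bases <- frag_ch[a_idx[cols][!is.na(a_idx[cols])]]
      if (length(bases) && any(bases != "T")) return("iii")
      if (any(cols %in% del_cols)) next
    }
    ## ii: inserted Us at a junction without a tract
    plain <- jm[jm$tract_len == 0L, , drop = FALSE]
    if (length(ins_cols) && nrow(plain)) {
      ins_bases <- frag_ch[a_idx[ins_cols]]
      for (r in seq_len(nrow(plain))) {
        sel <- near(plain$tpos[r], ins_cols)
        if (any(sel) && all(ins_bases[near(plain$tpos[r], ins_cols)] == "T"))
          return("ii")
      }
    }
    ## i: small indel or duplication at a junction
    for (r in seq_len(nrow(jm))) {
      if (any(near(jm$tpos[r], ins_cols)) || any(near(jm$tpos[r], del_cols)))
        return("i")
    }
  }
  if (length(ins_cols) || length(del_cols) || length(mismatch)) return("i")
  "none"
}
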