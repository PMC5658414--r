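## Cross-species comparison: ortholog MSAs, breakpoint projection, module
## fusion/fission detection, shared editing, identity statistics.

#' Center-star multiple alignment of ortholog sequences
#'
#' Pairwise global alignments of every sequence against a center sequence
#' (the longest; ties by name) are merged into a column-consistent multiple
#' alignment.  Deterministic for a fixed input order.
#'
#' @param seqs Named character vector (>= 2 sequences).
#' @param level `"nt"` or `"aa"`; `"aa"` translates before aligning.
#' @param code Genetic code for `level = "aa"` (see [translate_seq()]).
#' @return Named character vector of aligned rows (equal width, `-` gaps).
#' @export
build_ortholog_msa <- function(seqs, level = c("nt", "aa"),
                               code = "standard") {
  level <- match.arg(level)
  if (!length(seqs) || length(seqs) < 2L) stop("need at least two sequences")
  if (any(nchar(seqs) == 0L)) stop("empty input sequence")
  if (level == "aa") seqs <- vapply(seqs, translate_seq, "", code = code)
  nm <- names(seqs)
  ci <- order(-nchar(seqs), nm)[1]
  center <- seqs[[ci]]
  others <- setdiff(seq_along(seqs), ci)
  if (!length(others)) return(setNames(seqs, nm))
  submat <- if (level == "aa") "BLOSUM62" else NULL
  pats <- list(); gaps_center <- list()
  Lc <- nchar(center)
  for (i in others) {
    al <- if (level == "aa")
      Biostrings::pairwiseAlignment(
        Biostrings::AAString(seqs[[i]]), Biostrings::AAString(center),
        type = "global", substitutionMatrix = submat,
        gapOpening = 10, gapExtension = 0.5)
    else
      Biostrings::pairwiseAlignment(
        Biostrings::DNAString(seqs[[i]]), Biostrings::DNAString(center),
        type = "global",
        substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
          match = 2, mismatch = -1, baseOnly = TRUE),
        gapOpening = 6, gapExtension = 1)
    pa <- chars(as.character(Biostrings::alignedPattern(al)))
    su <- chars(as.character(Biostrings::alignedSubject(al)))
    ## gap counts before each center position 1..Lc and at the end
    g <- integer(Lc + 1L)
    cpos <- 0L
    run <- 0L
    for (k in seq_along(su)) {
      if (su[k] == "-") run <- run + 1L
      else { cpos <- cpos + 1L; g[cpos] <- run; run <- 0L }
    }
    g[Lc + 1L] <- run
    pats[[as.character(i)]] <- list(pa = pa, su = su, g = g)
  }
  G <- Reduce(pmax, lapply(pats, `[[`, "g"))
  ## rebuild each row with the merged gap pattern
  cench <- chars(center)
  build_center <- function() {
    out <- character(0)
    for (p in seq_len(Lc)) out <- c(out, rep("-", G[p]), cench[p])
    c(out, rep("-", G[Lc + 1L]))
  }
  rows <- list()
  rows[[nm[ci]]] <- paste(build_center(), collapse = "")
  for (i in others) {
    pp <- pats[[as.character(i)]]
    out <- character(0)
    cpos <- 0L; k <- 1L
    pend <- character(0)
    for (k in seq_along(pp$su)) {
      if (pp$su[k] == "-") { pend <- c(pend, pp$pa[k]); next }
      cpos <- cpos + 1L
      extra <- G[cpos] - length(pend)
      out <- c(out, rep("-", extra), pend, pp$pa[k])
      pend <- character(0)
    }
    extra <- G[Lc + 1L] - length(pend)
    out <- c(out, rep("-", extra), pend)
    rows[[nm[i]]] <- paste(out, collapse = "")
  }
  unlist(rows)[nm]
}

## column of the o-th residue (1-based o; 0 -> column 0) in an aligned row
residue_columns <- function(row) which(chars(row) != "-")

#' Project per-species junction offsets into alignment columns and match
#' them across species
#'
#' Junction offsets (0-based transcript positions) map to the alignment
#' column after their last upstream residue; junctions of different species
#' within `match_window` columns are matched into one group, and shifts are
#' reported in ungapped nt relative to the group's modal column.  Junctions
#' falling where all other species are gapped are flagged unalignable.
#'
#' @param msa Named aligned rows from [build_ortholog_msa()].
#' @param junctions Named list (per species) of integer junction offsets.
#' @param match_window Maximum column distance for matching (nt).
#' @return list(map = data.frame(species, offset, column, group, shift,
#'   unalignable), groups = data.frame(group, n_species, column)).
#' @export
project_breakpoints <- function(msa, junctions, match_window = 6L) {
  sp <- names(junctions)
  stopifnot(all(sp %in% names(msa)))
  rows <- list()
  for (s in sp) {
    rc <- residue_columns(msa[[s]])
    for (o in junctions[[s]]) {
      col <- if (o == 0L) 0L else rc[o]
      rows[[length(rows) + 1L]] <- data.frame(species = s, offset = o,
                                              column = col)
    }
  }
  map <- do.call(rbind, rows)
  map <- map[order(map$column, map$species), , drop = FALSE]
  ## single-linkage grouping along columns
  if (nrow(map)) {
    gaps <- diff(map$column) > match_window
    map$group <- cumsum(c(1L, as.integer(gaps)))
  }
  map$shift <- 0L
  map$unalignable <- FALSE
  ach <- lapply(msa, chars)
  width <- nchar(msa[[1]])
  for (g in unique(map$group)) {
    sel <- which(map$group == g)
    cols <- map$column[sel]
    modal <- as.integer(names(sort(table(cols), decreasing = TRUE))[1])
    for (k in sel) {
      s <- map$species[k]
      c1 <- min(map$column[k], modal); c2 <- max(map$column[k], modal)
      if (c2 > c1) {
        v <- ach[[s]][(c1 + 1L):c2]
        map$shift[k] <- sign(map$column[k] - modal) * sum(v != "-")
      }
      ## unalignable: every other species is gap across the local window
      w1 <- max(1L, map$column[k] - match_window %/% 2L)
      w2 <- min(width, map$column[k] + match_window %/% 2L)
      others <- setdiff(sp, s)
      if (length(others) && map$column[k] >= 1L) {
        allgap <- vapply(others, function(o)
          all(ach[[o]][w1:w2] == "-"), TRUE)
        if (all(allgap)) map$unalignable[k] <- TRUE
      }
    }
  }
  groups <- do.call(rbind, lapply(split(map, map$group), function(d)
    data.frame(group = d$group[1], n_species = length(unique(d$species)),
               column = as.integer(names(sort(table(d$column),
                                              decreasing = TRUE))[1]))))
  rownames(map) <- NULL
  list(map = map, groups = groups)
}

#' Detect module fusion/fission between species
#'
#' A junction present in species X but absent in species Y, with the
#' adjacent junction groups (or transcript ends) shared by both, indicates
#' that the two modules flanking it in X are fused in Y (equivalently, the
#' module is fissioned in X).  Direction labels are relative.
#'
#' @param bp Result of [project_breakpoints()] for one gene.
#' @param gene Gene name for the report.
#' @return data.frame of events: gene, species_with, species_without,
#'   ordinals (upstream module index in the species with the junction).
#' @export
detect_fusion_fission <- function(bp, gene = "") {
  map <- bp$map
  sp <- unique(map$species)
  out <- list()
  ## consider only internal junctions (offset > 0)
  internal <- map[map$offset > 0L & !map$unalignable, , drop = FALSE]
  for (g in unique(internal$group)) {
    have <- unique(internal$species[internal$group == g])
    lack <- setdiff(sp, have)
    if (!length(lack)) next
    gcol <- internal$column[internal$group == g][1]
    for (y in lack) {
      ## flanking junction groups shared by x and y
      for (x in have) {
        xj <- internal[internal$species == x, , drop = FALSE]
        ord <- which(sort(xj$column) == gcol)
        prev_ok <- TRUE; next_ok <- TRUE
        below <- internal[internal$column < gcol, , drop = FALSE]
        above <- internal[internal$column > gcol, , drop = FALSE]
        if (nrow(below)) {
          gprev <- below$group[which.max(below$column)]
          prev_ok <- y %in% internal$species[internal$group == gprev]
        }
        if (nrow(above)) {
          gnext <- above$group[which.min(above$column)]
          next_ok <- y %in% internal$species[internal$group == gnext]
        }
        if (prev_ok && next_ok) {
          out[[length(out) + 1L]] <- data.frame(
            gene = gene, species_with = x, species_without = y,
            type = "fusion", ordinal = if (length(ord)) ord[1] else NA_integer_)
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(gene = character(), species_with = character(),
                      species_without = character(), type = character(),
                      ordinal = integer()))
  res <- do.call(rbind, out)
  unique(res)
}

#' Shared and species-specific editing sites/clusters across species
#'
#' Sites are projected into alignment columns (same column and same kind =
#' homologous site); clusters are compared by overlapping projected spans.
#'
#' @param editing Named list (per species) of site tables with `kind`,
#'   `tpos` and for U-append rows `len`.
#' @param msa Aligned rows for the gene.
#' @param max_gap,min_sites Cluster parameters.
#' @return list(sites = data.frame(column, kind, n_species, species),
#'   clusters = data.frame(span columns, species sets)).
#' @export
shared_editing <- function(editing, msa, max_gap = 20L, min_sites = 2L) {
  sp <- names(editing)
  rows <- list()
  for (s in sp) {
    e <- editing[[s]]
    if (!nrow(e)) next
    rc <- residue_columns(msa[[s]])
    for (i in seq_len(nrow(e))) {
      col <- rc[e$tpos[i] + 1L]
      rows[[length(rows) + 1L]] <- data.frame(species = s, kind = e$kind[i],
                                              column = col, tpos = e$tpos[i])
    }
  }
  if (!length(rows))
    return(list(sites = data.frame(), clusters = data.frame()))
  tab <- do.call(rbind, rows)
  sites <- do.call(rbind, lapply(split(tab, paste(tab$column, tab$kind)),
                                 function(d) data.frame(
                                   column = d$column[1], kind = d$kind[1],
                                   n_species = length(unique(d$species)),
                                   species = paste(sort(unique(d$species)),
                                                   collapse = ","))))
  sites <- sites[order(sites$column), , drop = FALSE]
  rownames(sites) <- NULL
  ## clusters per species in column space, then overlap across species
  cl_rows <- list()
  for (s in sp) {
    d <- tab[tab$species == s & tab$kind != "U-append", , drop = FALSE]
    if (!nrow(d)) next
    cl <- cluster_sites(data.frame(pos = d$column), max_gap, min_sites)
    if (nrow(cl)) cl_rows[[s]] <- cbind(species = s, cl)
  }
  clusters <- data.frame()
  if (length(cl_rows)) {
    allc <- do.call(rbind, cl_rows)
    ## merge overlapping spans across species
    allc <- allc[order(allc$span_start), , drop = FALSE]
    grp <- integer(nrow(allc)); cur <- 1L; hi <- allc$span_end[1]
    grp[1] <- 1L
    for (i in seq_len(nrow(allc))[-1]) {
      if (allc$span_start[i] <= hi) { grp[i] <- cur; hi <- max(hi, allc$span_end[i]) }
      else { cur <- cur + 1L; grp[i] <- cur; hi <- allc$span_end[i] }
    }
    clusters <- do.call(rbind, lapply(split(allc, grp), function(d)
      data.frame(span_start = min(d$span_start), span_end = max(d$span_end),
                 n_species = length(unique(d$species)),
                 species = paste(sort(unique(d$species)), collapse = ","))))
    rownames(clusters) <- NULL
  }
  list(sites = sites, clusters = clusters)
}

#' Mean pairwise identity over an alignment region
#'
#' Average over all sequence pairs of identical columns / compared columns;
#' columns where either sequence of a pair is gapped are excluded from that
#' pair's comparison.  Reported to one decimal (percent).
#'
#' @param msa Named aligned rows.
#' @param region Optional integer vector of columns (default: all).
#' @return Percentage (1 decimal); `NA` with a warning when no pair has
#'   comparable columns.
#' @export
mean_pairwise_identity <- function(msa, region = NULL) {
  ch <- lapply(msa, chars)
  W <- length(ch[[1]])
  if (is.null(region)) region <- seq_len(W)
  nm <- names(msa)
  vals <- c()
  for (i in seq_along(nm)[-length(nm)]) {
    for (j in (i + 1L):length(nm)) {
      a <- ch[[i]][region]; b <- ch[[j]][region]
      ok <- a != "-" & b != "-"
      if (!any(ok)) next
      vals <- c(vals, mean(a[ok] == b[ok]))
    }
  }
  if (!length(vals)) {
    warning("no comparable columns in region")
    return(NA_real_)
  }
  round(100 * mean(vals), 1)
}
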