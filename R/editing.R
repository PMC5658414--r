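## RNA-editing detection: 3' U-appendage tracts, A-to-I and C-to-U
## substitution sites with genomic SNP subtraction, cluster calling, and the
## frame-compensation / A+T-equalization statistics.

#' Pair a transcript segment with its genomic module sequence
#'
#' Produces a gapless column pairing; the only tolerated length difference
#' is a single trailing RNA-only run (the 3' U-appendage tract).  Any other
#' indel is rejected, mirroring the discarded-indel rule of read-based
#' variant calling.
#'
#' @param transcript_segment RNA segment (cDNA sense).
#' @param genomic_module_seq Genomic module sequence, transcript sense.
#' @return list(dna, rna (character vectors of paired columns),
#'   trailing_rna (the RNA-only trailing run)).
#' @export
align_rna_dna <- function(transcript_segment, genomic_module_seq) {
  nr <- nchar(transcript_segment); nd <- nchar(genomic_module_seq)
  if (nr < nd)
    stop("unexplained indel: RNA segment shorter than genomic module")
  dna <- chars(genomic_module_seq)
  rna <- chars(substr(transcript_segment, 1L, nd))
  trailing <- if (nr > nd) substr(transcript_segment, nd + 1L, nr) else ""
  bad <- !edit_aware_match(dna, rna) & dna != rna
  ## a gapless pairing must be editing-coherent; a dense mismatch wall
  ## indicates a real indel shift
  if (mean(bad) > 0.25)
    stop("unexplained indel: segments do not pair gaplessly")
  list(dna = dna, rna = rna, trailing_rna = trailing)
}

#' Call substitution editing sites from paired columns
#'
#' DNA A vs RNA G is called A-to-I and DNA C vs RNA U is called C-to-U;
#' columns matching a known bi-allelic genomic SNP are subtracted (the
#' DNA-variant subtraction step), and any other mismatch is reported as a
#' rejected column, not called.
#'
#' @param pairs Result of [align_rna_dna()].
#' @param snp_table Optional data.frame with `pos` (0-based offset within
#'   the segment) or with `contig`/`pos` when `gmap` supplies genomic
#'   anchors; a column pairing equal to the SNP's allele pair is subtracted.
#' @param offset Transcript offset of the segment start (added to reported
#'   positions).
#' @param gmap Optional function(i) returning c(contig, gpos) for column i.
#' @return list(sites = data.frame(kind, pos), rejected = integer positions,
#'   subtracted = integer positions).
#' @export
call_substitutions <- function(pairs, snp_table = NULL, offset = 0L,
                               gmap = NULL) {
  dna <- pairs$dna; rna <- pairs$rna
  dif <- which(dna != rna)
  sites <- list(); rejected <- integer(0); subtracted <- integer(0)
  for (i in dif) {
    is_snp <- FALSE
    if (!is.null(snp_table) && nrow(snp_table)) {
      if (!is.null(gmap)) {
        gp <- gmap(i)
        hit <- snp_table$contig == gp[1] & snp_table$pos == as.integer(gp[2])
      } else {
        hit <- snp_table$pos == offset + i - 1L
      }
      is_snp <- any(hit)
    }
    if (is_snp) { subtracted <- c(subtracted, offset + i - 1L); next }
    if (dna[i] == "A" && rna[i] == "G") {
      sites[[length(sites) + 1L]] <- data.frame(kind = "A-to-I",
                                                pos = offset + i - 1L)
    } else if (dna[i] == "C" && rna[i] == "T") {
      sites[[length(sites) + 1L]] <- data.frame(kind = "C-to-U",
                                                pos = offset + i - 1L)
    } else {
      rejected <- c(rejected, offset + i - 1L)
    }
  }
  list(sites = if (length(sites)) do.call(rbind, sites) else
    data.frame(kind = character(), pos = integer()),
    rejected = rejected, subtracted = subtracted)
}

#' Measure a 3' U-appendage tract at a junction
#'
#' The tract length is the number of transcript Us not attributable to
#' genome-encoded Ts: the genomic module end absorbs as many Us as it
#' encodes (genome-encoded-T rule), the remainder is the appended tract.
#'
#' @param up_module_end Genomic sequence of the upstream module's 3' end
#'   (transcript sense), including any genome-encoded terminal Ts.
#' @param transcript_junction_region Transcript sequence starting where
#'   `up_module_end` starts (module terminus, tract and downstream).
#' @return Tract length (0 when no tract is present).
#' @export
call_u_appendage <- function(up_module_end, transcript_junction_region) {
  k <- nchar(up_module_end)
  if (substr(transcript_junction_region, 1L, k) != up_module_end)
    stop("transcript region does not begin with the genomic module end")
  ## genome-encoded Ts are already part of the module end: the tract is the
  ## residual transcript U run beyond the genome-encoded terminus
  rest <- chars(substr(transcript_junction_region, k + 1L,
                       nchar(transcript_junction_region)))
  run <- 0L
  while (run < length(rest) && rest[run + 1L] == "T") run <- run + 1L
  run
}

#' Group editing sites into clusters
#'
#' Single-linkage grouping of sites along the transcript: consecutive sites
#' at most `max_gap` nt apart join a cluster; clusters with fewer than
#' `min_sites` members are not reported.
#'
#' @param sites data.frame with `pos` (and any other columns), sorted or not.
#' @param max_gap Maximum gap between consecutive member sites (nt).
#' @param min_sites Minimum cluster size.
#' @return data.frame: cluster id, span_start, span_end, n_sites.
#' @export
cluster_sites <- function(sites, max_gap = 20L, min_sites = 2L) {
  if (!nrow(sites))
    return(data.frame(cluster = integer(), span_start = integer(),
                      span_end = integer(), n_sites = integer()))
  p <- sort(sites$pos)
  grp <- cumsum(c(1L, as.integer(diff(p) > max_gap)))
  out <- do.call(rbind, lapply(split(p, grp), function(v)
    data.frame(span_start = min(v), span_end = max(v), n_sites = length(v))))
  out <- out[out$n_sites >= min_sites, , drop = FALSE]
  if (!nrow(out))
    return(data.frame(cluster = integer(), span_start = integer(),
                      span_end = integer(), n_sites = integer()))
  out$cluster <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("cluster", "span_start", "span_end", "n_sites")]
}

#' Detect editing across annotated modules of a transcript set
#'
#' For every annotated module the transcript segment is paired with its
#' genomic sequence and substitution sites are called with SNP subtraction;
#' U-appendage tracts come from the junction table.  Candidate sites closer
#' than `edge_margin` to a module boundary are reported as uncertain and
#' excluded from the main call set (boundary placement there is not
#' sequence-resolvable).
#'
#' @param transcripts Named character vector.
#' @param modules `mm_modules` table (annotation or truth).
#' @param junctions Junction table with `gene`, `after_ordinal`, `tpos`,
#'   `tract_len`.
#' @param contigs Named list of [contig()] objects.
#' @param snps Optional SNP table with `contig`, `pos` (0-based genomic),
#'   or transcript-level `gene`,`tpos`.
#' @param edge_margin Exclusion margin at module boundaries (nt).
#' @param max_gap,min_sites Cluster parameters, see [cluster_sites()].
#' @return list(sites, utracts, clusters, rejected, uncertain, subtracted).
#' @export
call_editing <- function(transcripts, modules, junctions, contigs,
                         snps = NULL, edge_margin = 8L, max_gap = 20L,
                         min_sites = 2L) {
  site_rows <- list(); rej_rows <- list(); unc_rows <- list(); sub_rows <- list()
  for (tn in names(transcripts)) {
    m <- modules[modules$gene == tn, , drop = FALSE]
    if (!nrow(m)) next
    m <- m[order(m$ordinal), , drop = FALSE]
    for (i in seq_len(nrow(m))) {
      seg_t <- substr(transcripts[[tn]], m$tstart[i] + 1L, m$tend[i])
      seg_g <- module_seq(m, contigs, i)
      pr <- align_rna_dna(seg_t, seg_g)
      row <- m[i, ]
      gmap <- function(col) {
        c(row$contig_id, row_gpos(m, i, row$tstart + col - 1L))
      }
      res <- call_substitutions(pr, snp_table = snps, offset = m$tstart[i],
                                gmap = if (!is.null(snps) &&
                                           "contig" %in% names(snps)) gmap)
      if (nrow(res$sites)) {
        d5 <- res$sites$pos - m$tstart[i]
        d3 <- m$tend[i] - res$sites$pos
        edgy <- d5 < edge_margin | d3 <= edge_margin - 1L
        if (any(edgy))
          unc_rows[[length(unc_rows) + 1L]] <-
            cbind(gene = tn, res$sites[edgy, , drop = FALSE])
        if (any(!edgy))
          site_rows[[length(site_rows) + 1L]] <-
            cbind(gene = tn, res$sites[!edgy, , drop = FALSE])
      }
      if (length(res$rejected))
        rej_rows[[length(rej_rows) + 1L]] <-
          data.frame(gene = tn, pos = res$rejected)
      if (length(res$subtracted))
        sub_rows[[length(sub_rows) + 1L]] <-
          data.frame(gene = tn, pos = res$subtracted)
    }
  }
  sites <- if (length(site_rows)) do.call(rbind, site_rows) else
    data.frame(gene = character(), kind = character(), pos = integer())
  jn <- junctions[junctions$tract_len > 0L, , drop = FALSE]
  utracts <- if (nrow(jn)) data.frame(
    gene = jn$gene, after_ordinal = jn$after_ordinal, tpos = jn$tpos,
    length = jn$tract_len, terminal = jn$terminal) else data.frame(
      gene = character(), after_ordinal = integer(), tpos = integer(),
      length = integer(), terminal = logical())
  clusters <- do.call(rbind, lapply(split(sites, sites$gene), function(s) {
    cl <- cluster_sites(s, max_gap, min_sites)
    if (nrow(cl)) cbind(gene = s$gene[1], cl) else NULL
  }))
  list(sites = sites, utracts = utracts,
       clusters = clusters %||% data.frame(),
       rejected = if (length(rej_rows)) do.call(rbind, rej_rows) else
         data.frame(gene = character(), pos = integer()),
       uncertain = if (length(unc_rows)) do.call(rbind, unc_rows) else
         data.frame(gene = character(), kind = character(), pos = integer()),
       subtracted = if (length(sub_rows)) do.call(rbind, sub_rows) else
         data.frame(gene = character(), pos = integer()))
}

#' Cross-species U-tract frame compensation
#'
#' For internal modules of protein-coding genes the sum of module length and
#' appended tract length should differ between species by multiples of 3,
#' so that editing compensates sequence loss without breaking the reading
#' frame.
#'
#' @param tab data.frame with columns `gene`, `module` (ordinal), `species`,
#'   `module_len`, `tract_len`.
#' @return data.frame per gene/module: `delta_mod3` (0 = pass) for every
#'   species pair, with a `pass` flag.
#' @export
u_tract_frame_compensation <- function(tab) {
  out <- list()
  for (key in unique(paste(tab$gene, tab$module))) {
    s <- tab[paste(tab$gene, tab$module) == key, , drop = FALSE]
    if (nrow(s) < 2L) next
    tot <- s$module_len + s$tract_len
    for (i in seq_len(nrow(s) - 1L)) {
      for (j in (i + 1L):nrow(s)) {
        d <- (tot[i] - tot[j]) %% 3L
        out[[length(out) + 1L]] <- data.frame(
          gene = s$gene[1], module = s$module[1],
          species_a = s$species[i], species_b = s$species[j],
          delta_mod3 = d, pass = d == 0L)
      }
    }
  }
  if (!length(out))
    return(data.frame(gene = character(), module = integer(),
                      species_a = character(), species_b = character(),
                      delta_mod3 = integer(), pass = logical()))
  do.call(rbind, out)
}

at_fraction <- function(seq) {
  s <- chars(seq)
  mean(s %in% c("A", "T"))
}

#' A+T-content equalization by substitution editing
#'
#' Computes the across-species spread (max minus min, in percentage points,
#' rounded to the nearest integer) of A+T content on the unedited gene
#' sequences and on the edited transcripts.  Substitution editing that
#' pushes divergent genomes toward a common composition shrinks the spread.
#'
#' @param gene_seqs Named (by species) character vector of unedited gene
#'   (concatenated module) sequences.
#' @param edited_transcripts Named character vector of edited transcripts.
#' @return list(pre_diff_pct, post_diff_pct, at_gene, at_transcript).
#' @export
at_equalization <- function(gene_seqs, edited_transcripts) {
  if (length(gene_seqs) < 2L || length(edited_transcripts) < 2L)
    stop("at least two species required")
  if (any(nchar(gene_seqs) == 0L) || any(nchar(edited_transcripts) == 0L))
    stop("empty sequence")
  at_g <- vapply(gene_seqs, at_fraction, 0)
  at_t <- vapply(edited_transcripts, at_fraction, 0)
  list(pre_diff_pct = round(100 * (max(at_g) - min(at_g))),
       post_diff_pct = round(100 * (max(at_t) - min(at_t))),
       at_gene = at_g, at_transcript = at_t)
}
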