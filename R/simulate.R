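## Forward simulator of a diplonemid-style multipartite mitochondrial genome,
## transcriptome and complete ground truth.

rint <- function(lo, hi) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (hi < lo) stop("empty integer range")
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}

STOPS <- c("TAA", "TAG", "TGA")

#' Simulation configuration
#'
#' Defaults emulate the architecture reported for Diplonema/Rhynchopus
#' mitochondrial genomes: ~18 genes split into ~80 modules of 40-550 nt,
#' cassettes framed by >100-bp class motifs on circular chromosomes of
#' ~4-10 kbp, 3' U-appendage tracts up to ~50 nt, clustered A-to-I / C-to-U
#' substitution editing near junctions, rare bi-allelic SNPs
#' (~0.05-0.25% per coding bp) and low-rate trans-splicing errors.
#'
#' @param ... Named overrides of the defaults listed below.
#' @return A list of class `mm_sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_genes = 18L,
    gene_names = NULL,                  # default: known inventory, first n
    modules_per_gene_range = c(1L, 8L), # expected total ~81 modules
    module_length_range = c(40L, 550L),
    gene_length_range = c(40L, 3000L),
    n_classes = 2L,
    constant_region_length_range = c(3800L, 8500L),
    motif_length = 150L,
    class_divergence = 0.01,            # per-copy substitutions outside motifs
    modules_per_cassette_max = 1L,
    multi_module_cassette_fraction = 0,
    multi_cassette_fraction = 0,        # fraction of classes that are bi-cassette
    unclassified_fraction = 0.04,
    n_orphan_cassettes = 0L,
    orphan_length = 94L,
    nesting_events = 0L,
    nesting_overlap_bp = NULL,          # NULL = embedded module's own length
    opposite_overlap_events = 0L,
    u_append_site_rate = 0.25,
    u_tract_range = c(1L, 50L),
    subst_cluster_rate = 0.25,
    cluster_sites_range = c(2L, 8L),
    cluster_window = 30L,               # sites within this window of a junction
    junction_clearance = 16L,           # no editing within this of a boundary
    snp_rate = 0.0015,
    snp_clearance = 24L,
    splice_error_rates = c(0.005, 0.005, 0.005, 0.005),
    flank_length_range = c(10L, 60L),
    fragment_length_range = c(200L, 800L),
    fragment_depth = 10,
    fragment_flank_fraction = 0.3,
    fragment_noise_rate = 0,
    spacer_length_range = c(80L, 120L), # intra-array module spacing ~100 bp
    cassette_flank_range = c(50L, 300L),
    polya_length = 20L,
    gc = 0.35,
    coverage_mean = 250,
    n_chimeric = 0L,
    templates = NULL,
    seed = 1L)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  structure(cfg, class = "mm_sim_config")
}

#' D. papillatum-like preset: two chromosome classes, one module per
#' cassette, one cassette per chromosome.
#' @param ... Overrides passed to [sim_config()].
#' @export
preset_dpap <- function(...) {
  sim_config(n_classes = 2L, modules_per_cassette_max = 1L,
             multi_module_cassette_fraction = 0, multi_cassette_fraction = 0,
             unclassified_fraction = 0.04, nesting_events = 0L, ...)
}

#' D. ambulator-like preset: three classes, multi-module cassettes (up to
#' six modules ~100 bp apart), one bi-cassette class, unclassified module
#' arrays, short orphan cassettes and one nested module pair.
#' @param ... Overrides passed to [sim_config()].
#' @export
preset_damb <- function(...) {
  sim_config(n_classes = 3L, modules_per_cassette_max = 6L,
             multi_module_cassette_fraction = 0.25,
             multi_cassette_fraction = 1 / 3,
             unclassified_fraction = 0.12, n_orphan_cassettes = 6L,
             nesting_events = 1L, opposite_overlap_events = 1L, ...)
}

#' Partition a gene into contiguous module segments
#'
#' @param gene_len Gene length (nt of genome-encoded sequence).
#' @param n_modules Number of modules.
#' @param len_range Allowed module length range.
#' @return Integer vector of n_modules+1 cut offsets, `0 .. gene_len`.
#' @export
plan_fragmentation <- function(gene_len, n_modules, len_range = c(40L, 550L)) {
  lo <- len_range[1]; hi <- len_range[2]
  if (n_modules * lo > gene_len || n_modules * hi < gene_len)
    stop("infeasible partition: ", n_modules, " modules of ", lo, "-", hi,
         " nt cannot tile ", gene_len, " nt")
  lens <- integer(n_modules)
  rest <- gene_len
  for (i in seq_len(n_modules)) {
    k <- n_modules - i
    a <- max(lo, rest - k * hi)
    b <- min(hi, rest - k * lo)
    lens[i] <- rint(a, b)
    rest <- rest - lens[i]
  }
  cumsum(c(0L, lens))
}

#' Remove editing from a mature transcript segment
#'
#' Inverse of RNA editing at the sequence level: strips the 3' U-appendage
#' tract and reverts deamination edits (transcript G back to genomic A for
#' A-to-I; transcript U/T back to genomic C for C-to-U).  Re-applying the
#' events with [apply_editing()] restores the input exactly.
#'
#' @param mature_segment Transcript segment (cDNA sense, T for U).
#' @param events data.frame with columns `kind` (`U-append`, `A-to-I`,
#'   `C-to-U`), `pos` (0-based within segment) and `len` (tract length,
#'   U-append only).
#' @return Genomic module sequence.
#' @export
unedit_sequence <- function(mature_segment, events) {
  s <- chars(mature_segment)
  if (nrow(events)) {
    for (i in seq_len(nrow(events))) {
      e <- events[i, ]
      if (e$kind == "U-append") {
        idx <- (e$pos + 1L):(e$pos + e$len)
        if (any(idx > length(s)) || any(s[idx] != "T"))
          stop("U-append event does not cover a U tract")
        s <- s[-idx]
      } else if (e$kind == "A-to-I") {
        if (s[e$pos + 1L] != "G") stop("A-to-I event at non-G transcript base")
        s[e$pos + 1L] <- "A"
      } else if (e$kind == "C-to-U") {
        if (s[e$pos + 1L] != "T") stop("C-to-U event at non-U transcript base")
        s[e$pos + 1L] <- "C"
      } else stop("unknown editing kind: ", e$kind)
    }
  }
  paste(s, collapse = "")
}

#' Apply editing events to a genomic segment
#'
#' Forward editing: substitutes A->G (A-to-I) and C->T (C-to-U) and inserts
#' U tracts; positions refer to the edited (mature) coordinate system, so
#' applying events in increasing position order reproduces the transcript.
#'
#' @param genomic_segment Genomic (unedited) sequence.
#' @param events As in [unedit_sequence()].
#' @return Mature transcript segment.
#' @export
apply_editing <- function(genomic_segment, events) {
  s <- chars(genomic_segment)
  if (nrow(events)) {
    events <- events[order(events$pos), , drop = FALSE]
    for (i in seq_len(nrow(events))) {
      e <- events[i, ]
      if (e$kind == "U-append") {
        s <- append(s, rep("T", e$len), after = e$pos)
      } else if (e$kind == "A-to-I") {
        if (s[e$pos + 1L] != "A") stop("A-to-I event at non-A genomic base")
        s[e$pos + 1L] <- "G"
      } else if (e$kind == "C-to-U") {
        if (s[e$pos + 1L] != "C") stop("C-to-U event at non-C genomic base")
        s[e$pos + 1L] <- "T"
      }
    }
  }
  paste(s, collapse = "")
}

## ---------------------------------------------------------------------------
## gene planning and transcript generation

plan_genes <- function(cfg) {
  names <- cfg$gene_names %||% KNOWN_GENES[seq_len(min(cfg$n_genes, length(KNOWN_GENES)))]
  if (length(names) < cfg$n_genes)
    names <- c(names, paste0("g", seq_len(cfg$n_genes - length(names))))
  plans <- list()
  tnames <- vapply(cfg$templates %||% list(), `[[`, "", "name")
  for (g in names) {
    if (g %in% tnames) {
      tp <- cfg$templates[[match(g, tnames)]]
      n <- length(tp$core_lengths)
      plans[[g]] <- list(name = g, kind = tp$kind %||%
                           (if (g %in% KNOWN_RRNA) "rRNA" else "protein"),
                         n_mod = n, core_len = as.integer(tp$core_lengths),
                         tract = as.integer(tp$tracts %||% rep(0L, n)),
                         mature_fixed = tp$mature %||% NULL,
                         templated = TRUE)
    } else {
      n <- rint(cfg$modules_per_gene_range[1], cfg$modules_per_gene_range[2])
      glo <- max(cfg$gene_length_range[1], n * cfg$module_length_range[1])
      ghi <- min(cfg$gene_length_range[2], n * cfg$module_length_range[2])
      if (ghi < glo)
        stop("infeasible configuration: ", n, " modules of ",
             cfg$module_length_range[1], "-", cfg$module_length_range[2],
             " nt cannot realise a gene length in ",
             cfg$gene_length_range[1], "-", cfg$gene_length_range[2], " nt")
      gl <- rint(glo, ghi)
      cuts <- plan_fragmentation(gl, n, cfg$module_length_range)
      core <- diff(cuts)
      tract <- integer(n)
      for (j in seq_len(n)) {
        if (runif(1) < cfg$u_append_site_rate)
          tract[j] <- rint(cfg$u_tract_range[1], cfg$u_tract_range[2])
      }
      plans[[g]] <- list(name = g, kind = if (g %in% KNOWN_RRNA) "rRNA" else "protein",
                         n_mod = n, core_len = core, tract = tract,
                         mature_fixed = NULL, templated = FALSE)
    }
  }
  plans
}

## keep total coding length a codon multiple for protein genes by nudging the
## last module core; also forbid a terminal A so the poly-A boundary is crisp.
fix_frames <- function(plans, cfg) {
  for (g in names(plans)) {
    p <- plans[[g]]
    if (p$kind == "protein" && is.null(p$mature_fixed)) {
      tot <- sum(p$core_len) + sum(p$tract)
      d <- tot %% 3L
      p$core_len[p$n_mod] <- p$core_len[p$n_mod] - d
      plans[[g]] <- p
    }
  }
  plans
}

## transcript coordinates implied by the plan (generative, pre-canonical)
plan_coords <- function(p) {
  tstart <- integer(p$n_mod); tend <- integer(p$n_mod)
  pos <- 0L
  for (j in seq_len(p$n_mod)) {
    tstart[j] <- pos; tend[j] <- pos + p$core_len[j]
    pos <- tend[j] + p$tract[j]
  }
  list(tstart = tstart, tend = tend, total = pos)
}

## draw a transcript: module cores random, tract positions all T; protein
## genes are kept free of in-frame stop codons (bases inside `frozen` ranges
## are never redrawn; `preset` pins ranges to given sequences, used for
## nested modules copied out of their host).
draw_transcript <- function(p, cfg, frozen = NULL, preset = NULL) {
  co <- plan_coords(p)
  s <- chars(random_dna(co$total, cfg$gc))
  in_tract <- rep(FALSE, co$total)
  for (j in seq_len(p$n_mod)) {
    if (p$tract[j] > 0L)
      in_tract[(co$tend[j] + 1L):(co$tend[j] + p$tract[j])] <- TRUE
  }
  s[in_tract] <- "T"
  if (!is.null(preset)) {
    for (ps in preset)
      s[(ps$range[1] + 1L):ps$range[2]] <- chars(ps$seq)
  }
  frozen_mask <- rep(FALSE, co$total)
  if (!is.null(frozen)) for (fr in frozen) frozen_mask[(fr[1] + 1L):fr[2]] <- TRUE
  if (p$kind == "protein") {
    for (pass in 1:50) {
      seqstr <- paste(s, collapse = "")
      ncod <- floor(co$total / 3)
      codons <- substring(seqstr, 3 * seq_len(ncod) - 2, 3 * seq_len(ncod))
      bad <- which(codons %in% STOPS)
      if (!length(bad)) break
      for (b in bad) {
        idx <- (3L * b - 2L):(3L * b)
        free <- idx[!in_tract[idx] & !frozen_mask[idx]]
        if (!length(free)) next
        s[free] <- chars(random_dna(length(free), cfg$gc))
      }
    }
  }
  ## terminal module must not end in A (poly-A boundary convention)
  last <- co$tend[p$n_mod]
  if (p$tract[p$n_mod] == 0L && !frozen_mask[last] && s[last] == "A")
    s[last] <- sample(c("C", "G", "T"), 1L)
  paste(s, collapse = "")
}

## choose clustered substitution editing sites near junctions
place_editing <- function(p, co, mature, cfg, forbidden = NULL) {
  if (p$templated || p$n_mod < 1) return(data.frame())
  sites <- list()
  bases <- chars(mature)
  forb <- rep(FALSE, nchar(mature))
  if (!is.null(forbidden)) for (fr in forbidden) forb[(fr[1] + 1L):fr[2]] <- TRUE
  cl <- cfg$junction_clearance
  for (j in seq_len(p$n_mod - 1L)) {
    if (runif(1) >= cfg$subst_cluster_rate) next
    side <- sample(c("up", "down"), 1L)
    if (side == "up") {
      lo <- co$tstart[j] + cl; hi <- co$tend[j] - cl
      lo <- max(lo, co$tend[j] - cl - cfg$cluster_window)
    } else {
      lo <- co$tstart[j + 1L] + cl; hi <- co$tend[j + 1L] - cl
      hi <- min(hi, co$tstart[j + 1L] + cl + cfg$cluster_window)
    }
    if (hi - lo < 4L) next
    cand <- lo:hi
    cand <- cand[bases[cand + 1L] %in% c("G", "T") & !forb[cand + 1L]]
    if (length(cand) < 2L) next
    n <- min(rint(cfg$cluster_sites_range[1], cfg$cluster_sites_range[2]),
             length(cand))
    pos <- sort(sample(cand, n))
    kind <- ifelse(bases[pos + 1L] == "G", "A-to-I", "C-to-U")
    sites[[length(sites) + 1L]] <-
      data.frame(kind = kind, pos = pos, len = NA_integer_, junction = j)
  }
  if (!length(sites)) return(data.frame())
  do.call(rbind, sites)
}

## expressed bi-allelic SNPs: transcript carries allele2 at these positions
place_snps <- function(p, co, mature, cfg, taken) {
  if (p$templated || cfg$snp_rate <= 0) return(data.frame())
  bases <- chars(mature)
  n_target <- stats::rbinom(1L, sum(p$core_len), cfg$snp_rate)
  if (n_target == 0L) return(data.frame())
  ok <- rep(FALSE, nchar(mature))
  cl <- cfg$snp_clearance
  for (j in seq_len(p$n_mod)) {
    if (co$tend[j] - co$tstart[j] > 2L * cl)
      ok[(co$tstart[j] + cl + 1L):(co$tend[j] - cl)] <- TRUE
  }
  ok[taken + 1L] <- FALSE
  cand <- which(ok) - 1L
  if (!length(cand)) return(data.frame())
  pos <- sort(sample(cand, min(n_target, length(cand))))
  out <- data.frame(pos = pos, rna = bases[pos + 1L],
                    dna = NA_character_, confusable = NA)
  for (i in seq_len(nrow(out))) {
    r <- out$rna[i]
    conf <- runif(1) < 0.5
    d <- if (conf && r == "G") "A" else if (conf && r == "T") "C"
    else sample(setdiff(c("A", "C", "G", "T"),
                        c(r, if (r == "G") "A", if (r == "T") "C")), 1L)
    out$dna[i] <- d
    out$confusable[i] <- (d == "A" && r == "G") || (d == "C" && r == "T")
  }
  out
}

## ---------------------------------------------------------------------------
## nesting plan: embed whole modules inside larger host modules

plan_nesting <- function(plans, cfg) {
  n_same <- cfg$nesting_events
  n_opp <- cfg$opposite_overlap_events
  if (n_same + n_opp == 0L) return(list(plans = plans, events = list()))
  cand_host <- list(); cand_emb <- list()
  for (g in names(plans)) {
    p <- plans[[g]]
    if (p$kind != "protein" || p$templated) next
    ## dual-purpose nested modules are internal protein modules: both
    ## transcripts continue on either side of the shared stretch
    for (j in seq_len(p$n_mod)) {
      if (j == 1L || j == p$n_mod || p$n_mod < 3L) next
      if (p$core_len[j] >= 150L)
        cand_host[[length(cand_host) + 1L]] <- c(g, j)
      cand_emb[[length(cand_emb) + 1L]] <- c(g, j)
    }
  }
  events <- list()
  used <- character()
  for (k in seq_len(n_same + n_opp)) {
    strand_rel <- if (k <= n_same) "same" else "opposite"
    hosts <- Filter(function(h) !(h[1] %in% used), cand_host)
    if (!length(hosts)) break
    h <- hosts[[sample.int(length(hosts), 1L)]]
    hl <- plans[[h[1]]]$core_len[as.integer(h[2])]
    embs <- Filter(function(e)
      e[1] != h[1] && !(e[1] %in% used) &&
        (plans[[e[1]]]$core_len[as.integer(e[2])] <= hl - 20L ||
           !is.null(cfg$nesting_overlap_bp)), cand_emb)
    if (!length(embs)) next
    e <- embs[[sample.int(length(embs), 1L)]]
    ov <- cfg$nesting_overlap_bp %||% NULL
    if (!is.null(ov)) {
      if (ov > hl - 20L) stop("nesting_overlap_bp too large for host module")
      plans[[e[1]]]$core_len[as.integer(e[2])] <- as.integer(ov)
    }
    used <- c(used, h[1], e[1])
    if (strand_rel == "same") {
      ## the shared stretch codes in both genes: place the embedded module
      ## on a codon boundary of its own transcript so the overlap holds
      ## complete shared codons
      pe <- plans[[e[1]]]
      eo <- as.integer(e[2])
      pre <- sum(pe$core_len[seq_len(eo - 1L)]) +
        sum(pe$tract[seq_len(eo - 1L)])
      delta <- (3L - pre %% 3L) %% 3L
      if (delta > 0L) {
        adj <- if (pe$core_len[1] + delta <= 550L) delta else delta - 3L
        plans[[e[1]]]$core_len[1] <- pe$core_len[1] + adj
      }
    }
    events[[length(events) + 1L]] <-
      list(host_gene = h[1], host_ord = as.integer(h[2]),
           emb_gene = e[1], emb_ord = as.integer(e[2]),
           strand_rel = strand_rel, off = NA_integer_)
  }
  list(plans = plans, events = events)
}

## decide genomic offsets of embedded modules once coordinates are fixed
resolve_nesting_offsets <- function(events, plans, coords) {
  for (i in seq_along(events)) {
    ev <- events[[i]]
    hl <- plans[[ev$host_gene]]$core_len[ev$host_ord]
    bl <- plans[[ev$emb_gene]]$core_len[ev$emb_ord]
    lo <- 8L; hi <- hl - bl - 8L
    if (hi < lo) stop("host module too small for nested module")
    cand <- lo:hi
    if (ev$strand_rel == "same") {
      r <- (coords[[ev$emb_gene]]$tstart[ev$emb_ord] -
              coords[[ev$host_gene]]$tstart[ev$host_ord]) %% 3L
      cand <- cand[cand %% 3L == r]
      if (!length(cand)) stop("no frame-compatible offset for nested module")
    }
    events[[i]]$off <- cand[sample.int(length(cand), 1L)]
  }
  events
}

edit_df <- function() data.frame(kind = character(), pos = integer(),
                                 len = integer(), junction = integer())

## strand-aware coordinate surgery on a module row
row_extend_end <- function(mods, i, k) {
  if (mods$strand[i] == "+") mods$end[i] <- mods$end[i] + k
  else mods$start[i] <- mods$start[i] - k
  mods
}
row_trim_start <- function(mods, i, k) {
  if (mods$strand[i] == "+") mods$start[i] <- mods$start[i] + k
  else mods$end[i] <- mods$end[i] - k
  mods
}

## transcript position -> genomic position for a module row
row_gpos <- function(mods, i, tpos) {
  d <- tpos - mods$tstart[i]
  if (mods$strand[i] == "+") mods$start[i] + d else mods$end[i] - 1L - d
}

#' Verify simulator truth self-consistency
#'
#' Rebuilds every mature transcript from the genomic module sequences by
#' re-applying the recorded editing events (and expressed SNP alleles) and
#' compares byte-for-byte.
#'
#' @param truth An `mm_truth` object.
#' @param contigs Named list of [contig()] objects.
#' @return `TRUE` invisibly; stops on any inconsistency.
#' @export
verify_truth <- function(truth, contigs) {
  mods <- truth$modules
  for (g in names(truth$mature)) {
    m <- mods[mods$gene == g, , drop = FALSE]
    m <- m[order(m$ordinal), , drop = FALSE]
    jn <- truth$junctions[truth$junctions$gene == g, , drop = FALSE]
    parts <- character(0)
    for (j in seq_len(nrow(m))) {
      parts <- c(parts, module_seq(m, contigs, j))
      tl <- jn$tract_len[jn$after_ordinal == m$ordinal[j]]
      if (length(tl) && tl > 0L) parts <- c(parts, strrep("T", tl))
    }
    t <- chars(paste(parts, collapse = ""))
    ed <- truth$editing[truth$editing$gene == g &
                          truth$editing$kind != "U-append", , drop = FALSE]
    if (nrow(ed)) {
      for (i in seq_len(nrow(ed)))
        t[ed$tpos[i] + 1L] <- if (ed$kind[i] == "A-to-I") "G" else "T"
    }
    sn <- truth$snps[truth$snps$gene == g, , drop = FALSE]
    if (nrow(sn)) for (i in seq_len(nrow(sn))) t[sn$tpos[i] + 1L] <- sn$rna[i]
    got <- paste(t, collapse = "")
    if (!identical(got, truth$mature[[g]]))
      stop("truth inconsistency for gene ", g)
  }
  invisible(TRUE)
}

#' Simulate a complete dataset
#'
#' Generates mature transcripts with editing and expressed SNPs, assembles
#' circular chromosomes organised in motif-sharing classes holding cassettes
#' of one or more modules, canonicalizes junction truth under the package's
#' junction convention, and emits an overlapping transcript-fragment pool
#' with optional precursor flanks and injected trans-splicing errors.
#'
#' @param cfg An [sim_config()] object.
#' @return A list of class `mm_sim` with elements `contigs` (named list of
#'   [contig()]), `fragments` (named character vector) and `truth`
#'   (`mm_truth`).
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "mm_sim_config"))
  set.seed(cfg$seed)
  plans <- fix_frames(plan_genes(cfg), cfg)
  np <- plan_nesting(plans, cfg)
  plans <- fix_frames(np$plans, cfg)
  nesting <- np$events
  coords <- lapply(plans, plan_coords)
  nesting <- resolve_nesting_offsets(nesting, plans, coords)

  ## generation order: hosts before embedding genes
  emb_genes <- vapply(nesting, `[[`, "", "emb_gene")
  order_genes <- c(setdiff(names(plans), emb_genes), emb_genes)

  mature <- list(); editing <- list(); snps <- list()
  for (g in order_genes) {
    p <- plans[[g]]; co <- coords[[g]]
    frozen <- NULL; preset <- NULL; forbidden <- NULL
    if (g %in% emb_genes) {
      ev <- nesting[[match(g, emb_genes)]]
      hco <- coords[[ev$host_gene]]
      src <- substr(mature[[ev$host_gene]],
                    hco$tstart[ev$host_ord] + ev$off + 1L,
                    hco$tstart[ev$host_ord] + ev$off + p$core_len[ev$emb_ord])
      if (ev$strand_rel == "opposite") src <- reverse_complement(src)
      frozen <- list(c(co$tstart[ev$emb_ord], co$tend[ev$emb_ord]))
      preset <- list(list(range = frozen[[1]], seq = src))
      forbidden <- list(c(max(0L, co$tstart[ev$emb_ord] - 2L),
                          min(co$total, co$tend[ev$emb_ord] + 2L)))
    }
    host_of <- Filter(function(ev) ev$host_gene == g, nesting)
    for (ev in host_of) {
      bl <- plans[[ev$emb_gene]]$core_len[ev$emb_ord]
      forbidden <- c(forbidden, list(c(
        max(0L, co$tstart[ev$host_ord] + ev$off - 2L),
        min(co$total, co$tstart[ev$host_ord] + ev$off + bl + 2L))))
    }
    if (!is.null(p$mature_fixed)) {
      if (nchar(p$mature_fixed) != co$total)
        stop("template mature length mismatch for gene ", g)
      mature[[g]] <- toupper(p$mature_fixed)
      editing[[g]] <- edit_df(); snps[[g]] <- data.frame()
    } else {
      mt <- draw_transcript(p, cfg, frozen = frozen, preset = preset)
      if (g %in% emb_genes) {
        ## keep the nested overlap crisp: the embedded transcript must
        ## diverge from the host immediately after the copied window, so
        ## canonical attribution cannot extend the embedded module
        ev <- nesting[[match(g, emb_genes)]]
        hco <- coords[[ev$host_gene]]
        hpos <- hco$tstart[ev$host_ord] + ev$off + p$core_len[ev$emb_ord]
        epos <- co$tend[ev$emb_ord]
        if (hpos < hco$total && epos < co$total &&
            p$tract[ev$emb_ord] == 0L) {
          hbase <- substr(mature[[ev$host_gene]], hpos + 1L, hpos + 1L)
          if (substr(mt, epos + 1L, epos + 1L) == hbase) {
            repl <- setdiff(c("A", "C", "G", "T"), hbase)[1]
            substr(mt, epos + 1L, epos + 1L) <- repl
          }
        }
      }
      ed <- place_editing(p, co, mt, cfg, forbidden = forbidden)
      if (!is.data.frame(ed) || !nrow(ed)) ed <- edit_df()
      taken <- ed$pos
      for (fr in forbidden %||% list()) taken <- c(taken, fr[1]:(fr[2] - 1L))
      sn <- place_snps(p, co, mt, cfg, taken = unique(taken))
      mature[[g]] <- mt; editing[[g]] <- ed
      snps[[g]] <- if (is.data.frame(sn) && nrow(sn)) sn else data.frame()
    }
  }

  asm <- assemble_chromosomes(plans, coords, mature, editing, snps, nesting, cfg)
  res <- canonicalize_truth(asm, plans, coords, mature, editing, cfg)
  truth <- build_truth(res, asm, plans, mature, editing, snps, cfg)
  verify_truth(truth, asm$contigs)
  frg <- emit_fragments(mature, truth, plans, asm$contigs, cfg)
  truth$fragments <- frg$table
  truth$injected_errors <- frg$errors
  structure(list(contigs = asm$contigs, fragments = frg$pool, truth = truth),
            class = "mm_sim")
}

## ---------------------------------------------------------------------------
## genome assembly

mutate_seq <- function(seq, rate, protect = NULL) {
  if (rate <= 0) return(seq)
  s <- chars(seq)
  hit <- runif(length(s)) < rate
  if (!is.null(protect)) hit <- hit & !protect
  for (i in which(hit)) s[i] <- sample(setdiff(c("A", "C", "G", "T"), s[i]), 1L)
  paste(s, collapse = "")
}

## genomic (unedited, allele-1) sequence of one module core
genomic_core <- function(g, j, plans, coords, mature, editing, snps) {
  co <- coords[[g]]
  seg <- chars(substr(mature[[g]], co$tstart[j] + 1L, co$tend[j]))
  ed <- editing[[g]]
  if (nrow(ed)) {
    sel <- ed$kind != "U-append" & ed$pos >= co$tstart[j] & ed$pos < co$tend[j]
    for (i in which(sel))
      seg[ed$pos[i] - co$tstart[j] + 1L] <- if (ed$kind[i] == "A-to-I") "A" else "C"
  }
  sn <- snps[[g]]
  if (is.data.frame(sn) && nrow(sn)) {
    sel <- sn$pos >= co$tstart[j] & sn$pos < co$tend[j]
    for (i in which(sel)) seg[sn$pos[i] - co$tstart[j] + 1L] <- sn$dna[i]
  }
  paste(seg, collapse = "")
}

assemble_chromosomes <- function(plans, coords, mature, editing, snps,
                                 nesting, cfg) {
  emb_key <- vapply(nesting, function(ev) paste(ev$emb_gene, ev$emb_ord), "")
  units <- list()
  for (g in names(plans)) {
    for (j in seq_len(plans[[g]]$n_mod)) {
      if (paste(g, j) %in% emb_key) next
      units[[length(units) + 1L]] <- list(gene = g, ord = j)
    }
  }
  units <- units[sample.int(length(units))]

  ## group placeable modules into cassettes (multi-module arrays combine
  ## modules of different genes)
  cassettes <- list()
  while (length(units)) {
    if (runif(1) < cfg$multi_module_cassette_fraction && length(units) >= 2L &&
        cfg$modules_per_cassette_max >= 2L) {
      k <- rint(2L, min(cfg$modules_per_cassette_max, length(units)))
      take <- integer(0); seen <- character(0)
      for (i in seq_along(units)) {
        if (length(take) == k) break
        if (!(units[[i]]$gene %in% seen)) {
          take <- c(take, i); seen <- c(seen, units[[i]]$gene)
        }
      }
      if (length(take) < 2L) take <- 1L
    } else take <- 1L
    cassettes[[length(cassettes) + 1L]] <- units[take]
    units <- units[-take]
  }
  n_cass <- length(cassettes)

  ## allocate cassettes to unclassified chromosomes and classes
  u_n <- round(cfg$unclassified_fraction * n_cass)
  classified <- n_cass - u_n
  n_classes <- cfg$n_classes
  n_bi <- round(cfg$multi_cassette_fraction * n_classes)
  repeat {
    cpm <- c(rep(1L, n_classes - n_bi), rep(2L, n_bi))
    if (sum(2L * cpm) <= classified || n_classes == 1L) break
    n_classes <- n_classes - 1L
    n_bi <- min(n_bi, n_classes - 1L)
  }
  if (classified < 2L * sum(cpm))
    stop("infeasible config: too few cassettes (", n_cass,
         ") for ", n_classes, " chromosome classes")
  members <- rep(2L, n_classes)
  remaining <- classified - sum(members * cpm)
  w <- runif(n_classes)
  while (remaining > 0L) {
    ok <- which(cpm <= remaining)
    if (!length(ok)) { u_n <- u_n + remaining; remaining <- 0L; break }
    k <- sample(ok, 1L, prob = w[ok])
    members[k] <- members[k] + 1L
    remaining <- remaining - cpm[k]
  }
  ord <- order(members, decreasing = TRUE)
  members <- members[ord]; cpm <- cpm[ord]
  labels <- LETTERS[seq_len(n_classes)]

  contigs <- list(); mod_rows <- list(); cass_rows <- list()
  class_rows <- list(); class_motifs <- list()
  ci <- 0L
  orphan_class <- if (cfg$n_orphan_cassettes > 0L) {
    bi <- which(cpm == 2L)
    labels[if (length(bi)) bi[1] else n_classes]
  } else NA_character_

  build_cassette <- function(cass) {
    fl_up <- random_dna(rint(cfg$cassette_flank_range[1], cfg$cassette_flank_range[2]), cfg$gc)
    parts <- fl_up; offs <- list(); pos <- nchar(fl_up)
    for (i in seq_along(cass)) {
      u <- cass[[i]]
      core <- genomic_core(u$gene, u$ord, plans, coords, mature, editing, snps)
      strand <- sample(c("+", "-"), 1L)
      placed <- if (strand == "-") reverse_complement(core) else core
      offs[[i]] <- list(gene = u$gene, ord = u$ord, off = pos,
                        len = nchar(core), strand = strand)
      parts <- c(parts, placed); pos <- pos + nchar(core)
      if (i < length(cass)) {
        sp <- random_dna(rint(cfg$spacer_length_range[1], cfg$spacer_length_range[2]), cfg$gc)
        parts <- c(parts, sp); pos <- pos + nchar(sp)
      }
    }
    fl_dn <- random_dna(rint(cfg$cassette_flank_range[1], cfg$cassette_flank_range[2]), cfg$gc)
    list(seq = paste(c(parts, fl_dn), collapse = ""), offs = offs)
  }

  add_contig <- function(id, backbone, inserts, class_label) {
    ## inserts: list of (ip, built cassette or orphan seq, is_orphan)
    ips <- vapply(inserts, `[[`, 0L, "ip")
    o <- order(ips, decreasing = TRUE)
    seq <- backbone
    for (k in o) {
      ins <- inserts[[k]]
      seq <- paste0(substr(seq, 1L, ins$ip),
                    ins$seq,
                    substr(seq, ins$ip + 1L, nchar(seq)))
    }
    ## absolute offsets: process in ascending ip order
    shift <- 0L
    for (k in order(ips)) {
      ins <- inserts[[k]]
      abs0 <- ins$ip + shift
      cass_rows[[length(cass_rows) + 1L]] <<- data.frame(
        contig_id = id, start = abs0, end = abs0 + nchar(ins$seq),
        name = ins$name, n_modules = length(ins$offs %||% list()),
        orphan = isTRUE(ins$orphan))
      for (u in ins$offs %||% list()) {
        mod_rows[[length(mod_rows) + 1L]] <<- data.frame(
          gene = u$gene, ordinal = u$ord, contig_id = id,
          start = abs0 + u$off, end = abs0 + u$off + u$len,
          strand = u$strand)
      }
      shift <- shift + nchar(ins$seq)
    }
    cov <- pmax(1, rnorm(nchar(seq), cfg$coverage_mean, 0.05 * cfg$coverage_mean))
    contigs[[id]] <<- contig(id, seq, circular = TRUE, coverage = cov)
    class_rows[[length(class_rows) + 1L]] <<- data.frame(
      contig_id = id, class = class_label)
  }

  cass_i <- 0L
  next_cassette <- function() {
    cass_i <<- cass_i + 1L
    cassettes[[cass_i]]
  }

  for (k in seq_len(n_classes)) {
    L <- rint(cfg$constant_region_length_range[1], cfg$constant_region_length_range[2])
    cr <- random_dna(L, cfg$gc)
    ips <- if (cpm[k] == 2L) as.integer(c(floor(0.28 * L), floor(0.72 * L)))
    else as.integer(floor(0.5 * L))
    orphan_ip <- if (!is.na(orphan_class) && labels[k] == orphan_class)
      as.integer(floor(if (cpm[k] == 2L) 0.5 * L else 0.8 * L)) else NA_integer_
    protect <- rep(FALSE, L)
    for (ip in ips)
      protect[max(1L, ip - cfg$motif_length + 1L):min(L, ip + cfg$motif_length)] <- TRUE
    class_motifs[[labels[k]]] <- lapply(ips, function(ip) list(
      up = substr(cr, ip - cfg$motif_length + 1L, ip),
      down = substr(cr, ip + 1L, ip + cfg$motif_length)))
    orphan_template <- if (!is.na(orphan_ip)) random_dna(cfg$orphan_length, cfg$gc) else NULL
    orphans_left <- if (!is.na(orphan_ip)) cfg$n_orphan_cassettes else 0L
    for (m in seq_len(members[k])) {
      ci <- ci + 1L
      id <- sprintf("%s%02d", labels[k], m)
      backbone <- mutate_seq(cr, cfg$class_divergence, protect)
      inserts <- list()
      for (q in seq_len(cpm[k])) {
        bc <- build_cassette(next_cassette())
        inserts[[length(inserts) + 1L]] <-
          list(ip = ips[q], seq = bc$seq, offs = bc$offs,
               name = sprintf("cas_%s_%d", id, q), orphan = FALSE)
      }
      if (orphans_left > 0L) {
        inserts[[length(inserts) + 1L]] <-
          list(ip = orphan_ip, seq = mutate_seq(orphan_template, 0.05),
               offs = NULL, name = sprintf("orph_%s", id), orphan = TRUE)
        orphans_left <- orphans_left - 1L
      }
      add_contig(id, backbone, inserts, labels[k])
    }
  }
  ## unclassified chromosomes: unique backbone, one cassette (possibly array)
  u_m <- 0L
  while (cass_i < length(cassettes)) {
    u_m <- u_m + 1L
    id <- sprintf("U%02d", u_m)
    L <- rint(cfg$constant_region_length_range[1], cfg$constant_region_length_range[2])
    backbone <- random_dna(L, cfg$gc)
    bc <- build_cassette(next_cassette())
    add_contig(id, backbone, list(list(ip = as.integer(floor(0.5 * L)), seq = bc$seq,
                                       offs = bc$offs,
                                       name = sprintf("cas_%s_1", id),
                                       orphan = FALSE)), "U")
  }
  ## chimeric mito/nuclear contigs (assembly artifacts, no modules)
  chim_rows <- list()
  for (k in seq_len(cfg$n_chimeric)) {
    id <- sprintf("X%02d", k)
    mito <- random_dna(rint(2000L, 4000L), cfg$gc)
    nuc <- random_dna(rint(1500L, 3000L), 0.45)
    cov <- c(pmax(1, rnorm(nchar(mito), cfg$coverage_mean, 0.05 * cfg$coverage_mean)),
             pmax(0, rnorm(nchar(nuc), 5, 1)))
    contigs[[id]] <- contig(id, paste0(mito, nuc), circular = FALSE,
                            coverage = cov)
    chim_rows[[k]] <- data.frame(contig_id = id, split_point = nchar(mito))
  }

  mods <- do.call(rbind, mod_rows)
  ## embedded modules ride inside their hosts
  for (ev in nesting) {
    hi <- which(mods$gene == ev$host_gene & mods$ordinal == ev$host_ord)
    bl <- plans[[ev$emb_gene]]$core_len[ev$emb_ord]
    h <- mods[hi, ]
    if (h$strand == "+") {
      s0 <- h$start + ev$off
    } else {
      s0 <- h$end - ev$off - bl
    }
    strand <- if (ev$strand_rel == "same") h$strand else setdiff(c("+", "-"), h$strand)
    mods <- rbind(mods, data.frame(gene = ev$emb_gene, ordinal = ev$emb_ord,
                                   contig_id = h$contig_id, start = s0,
                                   end = s0 + bl, strand = strand))
  }
  ## attach transcript coordinates and frames
  mods$tstart <- NA_integer_; mods$tend <- NA_integer_
  mods$frame_offset <- NA_integer_
  for (i in seq_len(nrow(mods))) {
    g <- mods$gene[i]; j <- mods$ordinal[i]
    mods$tstart[i] <- coords[[g]]$tstart[j]
    mods$tend[i] <- coords[[g]]$tend[j]
    if (plans[[g]]$kind == "protein")
      mods$frame_offset[i] <- mods$tstart[i] %% 3L
  }
  mods <- mods[order(mods$gene, mods$ordinal), ]
  rownames(mods) <- NULL
  class(mods) <- c("mm_modules", "data.frame")
  ## the junction feeding into an embedded module must not absorb into the
  ## host: break any chance match of the upstream module's genomic flank
  ## with the transcript continuation
  for (ev in nesting) {
    if (ev$emb_ord <= 1L) next
    i_u <- which(mods$gene == ev$emb_gene & mods$ordinal == ev$emb_ord - 1L)
    r <- mods[i_u, ]
    tcont <- substr(mature[[ev$emb_gene]], r$tend + 1L, r$tend + 1L)
    ctg <- contigs[[r$contig_id]]
    gp <- if (r$strand == "+") r$end else r$start - 1L
    cur <- substr(ctg$seq, gp + 1L, gp + 1L)
    cur_t <- if (r$strand == "+") cur else
      c(A = "T", C = "G", G = "C", T = "A")[[cur]]
    partner <- c(G = "A", T = "C")[tcont]
    if (cur_t %in% c(tcont, partner[!is.na(partner)])) {
      ok <- setdiff(c("A", "C", "G", "T"),
                    c(tcont, partner[!is.na(partner)]))[1]
      new_base <- if (r$strand == "+") ok else
        c(A = "T", C = "G", G = "C", T = "A")[[ok]]
      seqv <- ctg$seq
      substr(seqv, gp + 1L, gp + 1L) <- new_base
      contigs[[r$contig_id]]$seq <- seqv
    }
  }
  list(contigs = contigs, modules = mods,
       cassettes = do.call(rbind, cass_rows),
       classes = do.call(rbind, class_rows),
       class_motifs = class_motifs,
       chimera = if (length(chim_rows)) do.call(rbind, chim_rows) else NULL,
       nesting = nesting)
}

## ---------------------------------------------------------------------------
## junction canonicalization: truth junctions follow the same convention the
## annotator applies (upstream-maximal attribution; genome-encoded T
## absorption at U-appendage junctions).

canonical_walk <- function(genomic, transcript) {
  gv <- chars(genomic); tv <- chars(transcript)
  n <- min(length(gv), length(tv))
  e <- 0L
  for (i in seq_len(n)) {
    if (gv[i] != tv[i]) break
    e <- i
  }
  e
}

backward_run <- function(genomic_before, transcript_before) {
  gv <- rev(chars(genomic_before)); tv <- rev(chars(transcript_before))
  n <- min(length(gv), length(tv))
  w <- 0L
  for (i in seq_len(n)) {
    if (gv[i] != tv[i]) break
    w <- i
  }
  w
}

canonicalize_truth <- function(asm, plans, coords, mature, editing, cfg) {
  mods <- asm$modules
  contigs <- asm$contigs
  jrows <- list()
  for (g in names(plans)) {
    p <- plans[[g]]
    T <- mature[[g]]; Tn <- nchar(T)
    for (j in seq_len(p$n_mod)) {
      i_j <- which(mods$gene == g & mods$ordinal == j)
      tract_gen <- p$tract[j]
      ctx <- module_context(mods, contigs, i_j, "down", 70L)
      tafter <- substr(T, mods$tend[i_j] + 1L, min(Tn, mods$tend[i_j] + 70L))
      absorbed <- if (nchar(tafter)) canonical_walk(ctx, tafter) else 0L
      if (absorbed > 0L) {
        mods <- row_extend_end(mods, i_j, absorbed)
        mods$tend[i_j] <- mods$tend[i_j] + absorbed
      }
      consumed <- min(absorbed, tract_gen)
      new_tract <- tract_gen - consumed
      into_next <- absorbed - consumed
      width <- 0L
      if (j < p$n_mod) {
        i_n <- which(mods$gene == g & mods$ordinal == j + 1L)
        if (into_next > 0L) {
          mods <- row_trim_start(mods, i_n, into_next)
          mods$tstart[i_n] <- mods$tstart[i_n] + into_next
        }
        ## downstream genome-T absorption: tract Us also encoded as Ts
        ## right before the downstream module's genomic start belong to
        ## the genome under maximal attribution
        if (new_tract > 0L) {
          gb0 <- module_context(mods, contigs, i_n, "up", new_tract)
          b <- backward_run(gb0, substr(T, mods$tstart[i_n] - new_tract + 1L,
                                        mods$tstart[i_n]))
          b <- min(b, new_tract)
          if (b > 0L) {
            mods <- row_trim_start(mods, i_n, -b)
            mods$tstart[i_n] <- mods$tstart[i_n] - b
            new_tract <- new_tract - b
          }
        }
        if (p$kind == "protein")
          mods$frame_offset[i_n] <- mods$tstart[i_n] %% 3L
        gb <- module_context(mods, contigs, i_n, "up", 10L)
        tb <- substr(T, max(1L, mods$tstart[i_n] - 9L), mods$tstart[i_n])
        width <- backward_run(gb, tb)
      }
      rule <- if (tract_gen > 0L) "downstream-of-T"
      else if (j == p$n_mod) "genome-encoded-terminal"
      else if (width == 0L && absorbed == 0L) "unique"
      else "upstream-maximal"
      jrows[[length(jrows) + 1L]] <- data.frame(
        gene = g, after_ordinal = j, tpos = mods$tend[i_j],
        tract_len = new_tract, width = width, rule = rule,
        terminal = (j == p$n_mod))
    }
  }
  list(mods = mods, junctions = do.call(rbind, jrows))
}

build_truth <- function(res, asm, plans, mature, editing, snps, cfg) {
  mods <- res$mods
  jn <- res$junctions
  ed_rows <- list()
  for (g in names(plans)) {
    ed <- editing[[g]]
    if (is.data.frame(ed) && nrow(ed)) {
      for (i in seq_len(nrow(ed))) {
        mi <- which(mods$gene == g & mods$tstart <= ed$pos[i] &
                      mods$tend > ed$pos[i])
        mi <- mi[1]
        ed_rows[[length(ed_rows) + 1L]] <- data.frame(
          kind = ed$kind[i], gene = g, tpos = ed$pos[i], len = NA_integer_,
          after_ordinal = NA_integer_, contig_id = mods$contig_id[mi],
          gpos = row_gpos(mods, mi, ed$pos[i]), strand = mods$strand[mi])
      }
    }
  }
  tr <- jn[jn$tract_len > 0L, , drop = FALSE]
  if (nrow(tr)) {
    for (i in seq_len(nrow(tr))) {
      mi <- which(mods$gene == tr$gene[i] & mods$ordinal == tr$after_ordinal[i])
      ed_rows[[length(ed_rows) + 1L]] <- data.frame(
        kind = "U-append", gene = tr$gene[i], tpos = tr$tpos[i],
        len = tr$tract_len[i], after_ordinal = tr$after_ordinal[i],
        contig_id = mods$contig_id[mi], gpos = NA_integer_,
        strand = mods$strand[mi])
    }
  }
  ed_df <- if (length(ed_rows)) do.call(rbind, ed_rows) else
    data.frame(kind = character(), gene = character(), tpos = integer(),
               len = integer(), after_ordinal = integer(),
               contig_id = character(), gpos = integer(), strand = character())
  sn_rows <- list()
  for (g in names(plans)) {
    sn <- snps[[g]]
    if (!is.data.frame(sn) || !nrow(sn)) next
    for (i in seq_len(nrow(sn))) {
      mi <- which(mods$gene == g & mods$tstart <= sn$pos[i] &
                    mods$tend > sn$pos[i])[1]
      gpos <- row_gpos(mods, mi, sn$pos[i])
      comp <- c(A = "T", C = "G", G = "C", T = "A")
      a1 <- sn$dna[i]; a2 <- sn$rna[i]
      if (mods$strand[mi] == "-") { a1 <- comp[[a1]]; a2 <- comp[[a2]] }
      sn_rows[[length(sn_rows) + 1L]] <- data.frame(
        gene = g, tpos = sn$pos[i], rna = sn$rna[i], dna = sn$dna[i],
        confusable = sn$confusable[i], contig_id = mods$contig_id[mi],
        gpos = gpos, allele1 = a1, allele2 = a2)
    }
  }
  sn_df <- if (length(sn_rows)) do.call(rbind, sn_rows) else
    data.frame(gene = character(), tpos = integer(), rna = character(),
               dna = character(), confusable = logical(),
               contig_id = character(), gpos = integer(),
               allele1 = character(), allele2 = character())
  gene_kind <- vapply(plans, `[[`, "", "kind")
  structure(list(
    modules = mods, junctions = jn,
    cassettes = asm$cassettes, classes = asm$classes,
    class_motifs = asm$class_motifs,
    mature = unlist(mature), gene_kind = gene_kind,
    editing = ed_df, snps = sn_df,
    chimera = asm$chimera,
    nesting = asm$nesting,
    seed = cfg$seed), class = "mm_truth")
}

## ---------------------------------------------------------------------------
## transcript fragment pool

emit_fragments <- function(mature, truth, plans, contigs, cfg) {
  pool <- character(0); rows <- list(); err_rows <- list()
  mods_all <- truth$modules
  for (g in names(mature)) {
    Tn <- nchar(mature[[g]]); Tseq <- mature[[g]]
    p <- plans[[g]]
    mods <- mods_all[mods_all$gene == g, , drop = FALSE]
    mods <- mods[order(mods$ordinal), , drop = FALSE]
    jn <- truth$junctions[truth$junctions$gene == g &
                            !truth$junctions$terminal, , drop = FALSE]
    flo <- min(cfg$fragment_length_range[1], Tn)
    fhi <- min(cfg$fragment_length_range[2], Tn)
    total <- 0L; pass <- 0L
    while (total < cfg$fragment_depth * Tn) {
      pass <- pass + 1L
      pos <- 0L; prev_end <- 0L
      repeat {
        len <- rint(flo, fhi)
        fstart <- max(0L, min(pos, Tn - len))
        fend <- fstart + len
        flank5 <- 0L; flank3 <- 0L
        seq5 <- ""; seq3 <- ""
        protected <- pass <= 2L && (fstart == 0L || fend >= Tn)
        ## unprocessed precursor flanks at internal module boundaries;
        ## snapping an end to a junction must keep the tiling chain
        ## connected, so the walk continues from the snapped end
        if (!protected && runif(1) < cfg$fragment_flank_fraction && nrow(jn)) {
          side <- sample(c(5L, 3L), 1L)
          flen <- rint(cfg$flank_length_range[1], cfg$flank_length_range[2])
          if (side == 3L) {
            cand <- jn$tpos[jn$tpos > fstart + 40L & jn$tpos < fend]
            if (length(cand)) {
              cut <- max(cand)
              jrow <- which(jn$tpos == cut)[1]
              mi <- which(mods$ordinal == jn$after_ordinal[jrow])
              seq3 <- module_context(mods, contigs, mi, "down", flen)
              fend <- cut; flank3 <- flen
            }
          } else if (fstart > 0L) {
            starts <- mods$tstart[mods$ordinal > 1L]
            cand <- starts[starts > fstart & starts < fend - 40L &
                             starts <= prev_end - 30L]
            if (length(cand)) {
              cut <- min(cand)
              mi <- which(mods$tstart == cut)
              seq5 <- module_context(mods, contigs, mi[1], "up", flen)
              fstart <- cut; flank5 <- flen
            }
          }
        }
        seq <- paste0(seq5, substr(Tseq, fstart + 1L, fend), seq3)
        polya <- FALSE
        if (fend == Tn && p$kind == "protein" && flank3 == 0L) {
          seq <- paste0(seq, strrep("A", cfg$polya_length))
          polya <- TRUE
        }
        if (cfg$fragment_noise_rate > 0)
          seq <- mutate_seq(seq, cfg$fragment_noise_rate)
        rows[[length(rows) + 1L]] <- data.frame(
          id = NA_character_, gene = g, tstart = fstart, tend = fend,
          flank5 = flank5, flank3 = flank3, polya = polya,
          error_type = 0L, error_junction = NA_integer_)
        pool <- c(pool, seq)
        total <- total + fend - fstart
        prev_end <- fend
        if (fend >= Tn) break
        ov <- min(rint(60L, 150L), fend - fstart - 10L)
        pos <- fend - ov
      }
      if (pass > 4L * cfg$fragment_depth) break
    }
  }
  ## inject trans-splicing errors of the four canonical types
  tab <- do.call(rbind, rows)
  n <- nrow(tab)
  genes <- unique(tab$gene)
  eligible <- which(tab$flank5 == 0L & tab$flank3 == 0L & !tab$polya &
                      tab$tstart > 0L)
  jn_all <- truth$junctions[!truth$junctions$terminal, , drop = FALSE]
  inner_junction <- function(i, need_tract = NA, margin = 20L) {
    jg <- jn_all[jn_all$gene == tab$gene[i], , drop = FALSE]
    if (!is.na(need_tract))
      jg <- jg[(jg$tract_len > 0L) == need_tract, , drop = FALSE]
    jg <- jg[jg$tpos > tab$tstart[i] + margin &
               jg$tpos + jg$tract_len < tab$tend[i] - margin, , drop = FALSE]
    if (!nrow(jg)) return(NULL)
    jg[sample.int(nrow(jg), 1L), ]
  }
  for (type in 1:4) {
    rate <- cfg$splice_error_rates[type]
    if (rate <= 0 || !length(eligible)) next
    n_err <- stats::rbinom(1L, length(eligible), rate)
    if (n_err == 0L) next
    picks <- sample(eligible, min(n_err, length(eligible)))
    eligible <- setdiff(eligible, picks)
    for (i in picks) {
      g <- tab$gene[i]
      if (type == 4L && length(genes) >= 2L) {
        g2 <- sample(setdiff(genes, g), 1L)
        j1 <- jn_all[jn_all$gene == g, , drop = FALSE]
        j2m <- mods_all[mods_all$gene == g2 & mods_all$ordinal > 1L, , drop = FALSE]
        if (!nrow(j1) || !nrow(j2m)) next
        c1 <- j1$tpos[sample.int(nrow(j1), 1L)]
        c2 <- j2m$tstart[sample.int(nrow(j2m), 1L)]
        a <- substr(truth$mature[[g]], max(1L, c1 - rint(100L, 250L)), c1)
        b <- substr(truth$mature[[g2]], c2 + 1L,
                    min(nchar(truth$mature[[g2]]), c2 + rint(100L, 250L)))
        pool[i] <- paste0(a, b)
        tab$error_type[i] <- 4L; tab$error_junction[i] <- c1
        err_rows[[length(err_rows) + 1L]] <- data.frame(
          frag = i, type = 4L, gene = g, gene2 = g2, junction = c1)
      } else if (type == 3L) {
        jj <- inner_junction(i, need_tract = TRUE)
        if (is.null(jj)) next
        mi <- which(mods_all$gene == g & mods_all$ordinal == jj$after_ordinal)
        flank <- module_context(mods_all, contigs, mi, "down", jj$tract_len)
        off1 <- jj$tpos - tab$tstart[i]
        off2 <- jj$tpos + jj$tract_len - tab$tstart[i]
        pool[i] <- paste0(substr(pool[i], 1L, off1), flank,
                          substr(pool[i], off2 + 1L, nchar(pool[i])))
        tab$error_type[i] <- 3L; tab$error_junction[i] <- jj$tpos
        err_rows[[length(err_rows) + 1L]] <- data.frame(
          frag = i, type = 3L, gene = g, gene2 = NA, junction = jj$tpos)
      } else if (type == 2L) {
        jj <- inner_junction(i, need_tract = FALSE)
        if (is.null(jj)) next
        k <- rint(1L, 3L)
        off <- jj$tpos - tab$tstart[i]
        pool[i] <- paste0(substr(pool[i], 1L, off), strrep("T", k),
                          substr(pool[i], off + 1L, nchar(pool[i])))
        tab$error_type[i] <- 2L; tab$error_junction[i] <- jj$tpos
        err_rows[[length(err_rows) + 1L]] <- data.frame(
          frag = i, type = 2L, gene = g, gene2 = NA, junction = jj$tpos)
      } else {
        jj <- inner_junction(i, need_tract = FALSE)
        if (is.null(jj)) next
        k <- rint(1L, 3L)
        off <- jj$tpos - tab$tstart[i]
        pool[i] <- if (runif(1) < 0.5) {
          paste0(substr(pool[i], 1L, off - k),
                 substr(pool[i], off + 1L, nchar(pool[i])))
        } else {
          paste0(substr(pool[i], 1L, off),
                 substr(pool[i], off - k + 1L, off),
                 substr(pool[i], off + 1L, nchar(pool[i])))
        }
        tab$error_type[i] <- 1L; tab$error_junction[i] <- jj$tpos
        err_rows[[length(err_rows) + 1L]] <- data.frame(
          frag = i, type = 1L, gene = g, gene2 = NA, junction = jj$tpos)
      }
    }
  }
  ord <- sample.int(n)
  pool <- pool[ord]; tab <- tab[ord, , drop = FALSE]
  tab$id <- sprintf("frag%04d", seq_len(n))
  names(pool) <- tab$id
  if (length(err_rows)) {
    errs <- do.call(rbind, err_rows)
    errs$frag <- tab$id[match(errs$frag, ord)]
  } else {
    errs <- data.frame(frag = character(), type = integer(), gene = character(),
                       gene2 = character(), junction = integer())
  }
  rownames(tab) <- NULL
  list(pool = pool, table = tab, errors = errs)
}

#' Write a simulated dataset to a directory
#'
#' Emits `contigs.fasta`, `fragments.fasta`, `truth.json`, `truth.gff3`
#' (modules), `truth_edits.tsv`, `truth_classes.tsv`, `coverage.tsv` and
#' `snps.tsv`.
#'
#' @param sim An `mm_sim` object from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_contigs_fasta(sim$contigs, file.path(dir, "contigs.fasta"))
  write_seqs_fasta(sim$fragments, file.path(dir, "fragments.fasta"))
  write_truth_json(sim$truth, file.path(dir, "truth.json"))
  write_modules_gff3(sim$truth$modules, file.path(dir, "truth.gff3"))
  write.table(sim$truth$editing, file.path(dir, "truth_edits.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$truth$classes, file.path(dir, "truth_classes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_coverage_tsv(sim$contigs, file.path(dir, "coverage.tsv"))
  sn <- sim$truth$snps
  snp_out <- data.frame(contig = sn$contig_id, pos = sn$gpos + 1L,
                        allele1 = sn$allele1, allele2 = sn$allele2)
  write.table(snp_out, file.path(dir, "snps.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
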