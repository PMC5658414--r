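## Pipeline configuration and the stage driver tying reconstruction,
## annotation, classification and editing detection together.

pipeline_defaults <- function() list(
  min_overlap = 20L,        # OLC: minimum aligned overlap core (nt)
  min_identity = 0.98,      # OLC: minimum overlap identity
  max_end_skip = 60L,       # OLC: tolerated unprocessed-flank length (nt)
  map_min_len = 30L,        # annotation: minimum module hit length
  map_min_identity = 0.9,   # annotation: minimum hit identity
  motif_min_len = 100L,     # classification: >100 bp motif rule
  motif_min_identity = 0.90,# classification: >90% identity rule
  cassette_window = 100L,   # cassette boundary smoothing window (bp)
  cassette_threshold = 0.90,# cassette boundary identity threshold
  cluster_max_gap = 20L,    # editing clusters: max intra-cluster gap (nt)
  cluster_min_sites = 2L,   # editing clusters: minimum sites
  edge_margin = 8L,         # editing: boundary-uncertain margin (nt)
  u_tract_max = 50L,        # sanity bound on U-appendage tract length
  junction_ambiguity_max = 6L,
  chimera_high_floor = 200, # coverage of validated mitochondrial contigs
  chimera_low_ceiling = 100,# coverage ceiling of nuclear moieties
  seed = 1L)

pipeline_ranges <- list(
  min_overlap = c(5, 1000), min_identity = c(0.5, 1), max_end_skip = c(0, 500),
  map_min_len = c(10, 1000), map_min_identity = c(0.5, 1),
  motif_min_len = c(20, 5000), motif_min_identity = c(0.5, 1),
  cassette_window = c(10, 2000), cassette_threshold = c(0.5, 1),
  cluster_max_gap = c(1, 500), cluster_min_sites = c(1, 50),
  edge_margin = c(0, 50), u_tract_max = c(1, 500),
  junction_ambiguity_max = c(0, 50),
  chimera_high_floor = c(1, 1e6), chimera_low_ceiling = c(0, 1e6),
  seed = c(0, 2^31 - 1))

#' Validate a pipeline configuration
#'
#' Reads a flat YAML key-value file (or a named list), applies documented
#' defaults, rejects unknown keys and range-checks every threshold.  The
#' defaults echo the field's standard thresholds: motifs of >100 bp at >90%
#' identity, up to 6 nt junction ambiguity, U tracts up to ~50 nt.
#'
#' @param path Path to a YAML file, a named list, or `NULL` for defaults.
#' @return A validated config list of class `mm_pipeline_config`.
#' @export
validate_config <- function(path = NULL) {
  cfg <- pipeline_defaults()
  user <- if (is.null(path)) list()
  else if (is.list(path)) path
  else {
    if (!file.exists(path)) stop("config file not found: ", path)
    yaml::read_yaml(path) %||% list()
  }
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg[names(user)] <- user
  for (k in names(pipeline_ranges)) {
    r <- pipeline_ranges[[k]]
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < r[1] || v > r[2])
      stop("config value out of range for '", k, "': ", v,
           " (allowed ", r[1], "..", r[2], ")")
  }
  structure(cfg, class = "mm_pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stage order mirrors the analysis workflow: transcript reconstruction
#' (when a fragment pool is given), module annotation, chromosome
#' classification, editing detection, and a summary with architecture
#' counts and editing tallies.  Deterministic given the seed.
#'
#' @param contigs Named list of [contig()] objects or a FASTA path.
#' @param fragments Optional named character vector or FASTA path (pool of
#'   partial transcripts; reconstructed first).
#' @param transcripts Optional named character vector or FASTA path of
#'   mature transcripts (skips reconstruction).
#' @param snps Optional SNP table (data.frame or TSV path with 1-based
#'   `pos`).
#' @param coverage Optional coverage table path or named list.
#' @param out Optional output directory; when given, result files are
#'   written there.
#' @param config A [validate_config()] result, a YAML path, or `NULL`.
#' @return list(transcripts, annotation, classification, editing, summary).
#' @export
run_pipeline <- function(contigs, fragments = NULL, transcripts = NULL,
                         snps = NULL, coverage = NULL, out = NULL,
                         config = NULL) {
  cfg <- if (inherits(config, "mm_pipeline_config")) config
  else validate_config(config)
  set.seed(cfg$seed)
  is_path <- function(x) is.character(x) && length(x) == 1L && is.null(names(x))
  if (is_path(contigs)) contigs <- read_contigs_fasta(contigs)
  if (is_path(fragments)) fragments <- read_seqs_fasta(fragments)
  if (is_path(transcripts)) transcripts <- read_seqs_fasta(transcripts)
  if (is_path(snps)) {
    snps <- read_snp_tsv(snps)
    snps$pos <- snps$pos - 1L   # internal 0-based
  }
  if (is_path(coverage)) {
    cov <- read_coverage_tsv(coverage)
    for (id in names(cov))
      if (id %in% names(contigs)) contigs[[id]]$coverage <- cov[[id]]
  }
  if (is.null(transcripts)) {
    if (is.null(fragments)) stop("need either fragments or transcripts")
    message("[reconstruct] ", length(fragments), " fragments")
    tr <- reconstruct_transcripts(fragments, cfg$min_overlap,
                                  cfg$min_identity, cfg$max_end_skip)
    transcripts <- vapply(tr, `[[`, "", "seq")
  } else {
    tr <- NULL
    transcripts <- vapply(transcripts, function(s) trim_polya(s)$seq, "")
  }
  message("[annotate] ", length(transcripts), " transcripts vs ",
          length(contigs), " contigs")
  ann <- annotate_transcripts(transcripts, contigs, cfg$map_min_len,
                              cfg$map_min_identity)
  if (is.null(ann$modules)) stop("annotation produced no modules")
  message("[classify] ", nrow(ann$modules), " modules")
  cls <- classify_chromosomes(contigs, ann$modules, cfg$motif_min_len,
                              cfg$motif_min_identity, cfg$cassette_window)
  message("[edits]")
  ed <- call_editing(transcripts, ann$modules, ann$junctions, contigs,
                     snps = snps, edge_margin = cfg$edge_margin,
                     max_gap = cfg$cluster_max_gap,
                     min_sites = cfg$cluster_min_sites)
  summary <- list(
    n_transcripts = length(transcripts),
    n_modules = nrow(ann$modules),
    architecture = cls$summary$totals,
    n_editing_sites = nrow(ed$sites),
    n_sites_AtoI = sum(ed$sites$kind == "A-to-I"),
    n_sites_CtoU = sum(ed$sites$kind == "C-to-U"),
    n_u_tracts = nrow(ed$utracts),
    n_clusters = if (is.data.frame(ed$clusters)) nrow(ed$clusters) else 0L)
  res <- list(reconstruction = tr, transcripts = transcripts,
              annotation = ann, classification = cls, editing = ed,
              summary = summary)
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    write_seqs_fasta(transcripts, file.path(out, "transcripts.fasta"))
    write_modules_gff3(ann$modules, file.path(out, "modules.gff3"))
    write.table(ann$junctions, file.path(out, "junctions.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(cls$classes, file.path(out, "classes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (nrow(cls$cassettes)) {
      cb <- cls$cassettes
      cb$name <- sprintf("cassette%02d", seq_len(nrow(cb)))
      write_cassettes_bed(cb, file.path(out, "cassettes.bed"))
    }
    write.table(ed$sites, file.path(out, "editing_sites.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(ed$utracts, file.path(out, "utracts.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(summary, file.path(out, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}
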