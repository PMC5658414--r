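#' Read contigs from FASTA
#'
#' Multi-record FASTA; circularity is flagged with the header token
#' `circular=true`.  Per-base coverage, if available, travels in a separate
#' TSV (see [read_coverage_tsv()]).
#'
#' @param path FASTA file.
#' @return Named list of [contig()] objects.
#' @export
read_contigs_fasta <- function(path) {
  if (!file.exists(path)) stop("input FASTA not found: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  out <- list()
  for (i in seq_along(ss)) {
    hdr <- names(ss)[i]
    toks <- strsplit(hdr, "\\s+")[[1]]
    id <- toks[1]
    circ <- any(grepl("^circular=true$", toks[-1], ignore.case = TRUE))
    out[[id]] <- contig(id, as.character(ss[[i]]), circular = circ)
  }
  out
}

#' Write contigs to FASTA
#' @param contigs Named list of [contig()] objects.
#' @param path Output file.
#' @export
write_contigs_fasta <- function(contigs, path) {
  ss <- Biostrings::DNAStringSet(vapply(contigs, `[[`, "", "seq"))
  names(ss) <- vapply(contigs, function(c)
    if (c$circular) paste0(c$id, " circular=true") else c$id, "")
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Write plain sequences (fragments, transcripts) to FASTA
#' @param seqs Named character vector of sequences.
#' @param path Output file.
#' @export
write_seqs_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Read plain sequences from FASTA
#' @param path FASTA file.
#' @return Named character vector.
#' @export
read_seqs_fasta <- function(path) {
  if (!file.exists(path)) stop("input FASTA not found: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(ss), vapply(strsplit(names(ss), "\\s+"), `[[`, "", 1))
}

#' Write a module table as GFF3
#'
#' Internal 0-based half-open coordinates are converted to GFF3's 1-based
#' inclusive convention; gene, ordinal and frame offset travel as attributes.
#'
#' @param mods An `mm_modules` table.
#' @param path Output file.
#' @export
write_modules_gff3 <- function(mods, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = mods$contig_id,
    ranges = IRanges::IRanges(start = mods$start + 1L, end = mods$end),
    strand = mods$strand)
  S4Vectors::mcols(gr)$type <- "gene_module"
  S4Vectors::mcols(gr)$source <- "mitomosaic"
  S4Vectors::mcols(gr)$ID <- paste0(mods$gene, "-m", mods$ordinal)
  S4Vectors::mcols(gr)$gene <- mods$gene
  S4Vectors::mcols(gr)$ordinal <- mods$ordinal
  S4Vectors::mcols(gr)$frame_offset <- ifelse(is.na(mods$frame_offset), ".",
                                              as.character(mods$frame_offset))
  S4Vectors::mcols(gr)$tstart <- ifelse(is.na(mods$tstart), ".",
                                        as.character(mods$tstart))
  S4Vectors::mcols(gr)$tend <- ifelse(is.na(mods$tend), ".",
                                      as.character(mods$tend))
  rtracklayer::export.gff3(gr, path)
  invisible(path)
}

#' Read a module table from GFF3 written by [write_modules_gff3()]
#' @param path GFF3 file.
#' @return An `mm_modules` table.
#' @export
read_modules_gff3 <- function(path) {
  if (!file.exists(path)) stop("input GFF3 not found: ", path)
  gr <- rtracklayer::import(path)
  mc <- S4Vectors::mcols(gr)
  num_or_na <- function(x) suppressWarnings(as.integer(ifelse(x == ".", NA, x)))
  module_table(
    gene = as.character(mc$gene),
    ordinal = as.integer(mc$ordinal),
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    frame_offset = num_or_na(mc$frame_offset),
    tstart = num_or_na(mc$tstart),
    tend = num_or_na(mc$tend))
}

#' Write cassette intervals as BED (0-based half-open, as internal coords)
#' @param cassettes data.frame with contig_id, start, end, name.
#' @param path Output file.
#' @export
write_cassettes_bed <- function(cassettes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = cassettes$contig_id,
    ranges = IRanges::IRanges(start = cassettes$start + 1L,
                              end = cassettes$end),
    name = cassettes$name)
  rtracklayer::export.bed(gr, path)
  invisible(path)
}

#' Read cassettes from BED
#' @param path BED file.
#' @return data.frame with contig_id, start, end, name (0-based half-open).
#' @export
read_cassettes_bed <- function(path) {
  if (!file.exists(path)) stop("input BED not found: ", path)
  gr <- rtracklayer::import.bed(path)
  data.frame(contig_id = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             name = if (!is.null(gr$name)) gr$name else NA_character_,
             stringsAsFactors = FALSE)
}

#' Read a per-base coverage table
#'
#' TSV with columns `contig`, `pos` (1-based) and `coverage`.
#'
#' @param path TSV file.
#' @return Named list of numeric vectors.
#' @export
read_coverage_tsv <- function(path) {
  if (!file.exists(path)) stop("coverage table not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("contig", "pos", "coverage") %in% names(df)))
  lapply(split(df, df$contig), function(d) d$coverage[order(d$pos)])
}

#' Write a per-base coverage table
#' @param contigs Named list of [contig()] objects carrying `$coverage`.
#' @param path Output TSV.
#' @export
write_coverage_tsv <- function(contigs, path) {
  rows <- lapply(contigs, function(c) {
    if (is.null(c$coverage)) return(NULL)
    data.frame(contig = c$id, pos = seq_along(c$coverage),
               coverage = c$coverage, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genomic SNP table
#'
#' TSV with columns `contig`, `pos` (1-based), `allele1`, `allele2`; the
#' contig sequence carries `allele1`.  Diplonemid mitochondrial SNPs are
#' almost exclusively bi-allelic, and only the bi-allelic form is modelled.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_snp_tsv <- function(path) {
  if (!file.exists(path)) stop("SNP table not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("contig", "pos", "allele1", "allele2") %in% names(df)))
  df
}

#' Serialize a simulation truth table to JSON
#' @param truth An `mm_truth` object.
#' @param path Output JSON file.
#' @export
write_truth_json <- function(truth, path) {
  x <- unclass(truth)
  ## named vectors must serialize as objects, not bare arrays
  x$mature <- as.list(x$mature)
  x$gene_kind <- as.list(x$gene_kind)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a truth table back from JSON
#' @param path JSON file.
#' @return An `mm_truth` object.
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ## data.frame-valued members come back as data.frames via simplifyVector
  if (!is.null(x$modules)) class(x$modules) <- c("mm_modules", "data.frame")
  x$mature <- unlist(x$mature)
  x$gene_kind <- unlist(x$gene_kind)
  structure(x, class = "mm_truth")
}
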