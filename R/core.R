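#' @useDynLib mitomosaic, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import Biostrings
#' @importFrom stats runif rnorm rbinom setNames
#' @importFrom utils read.delim write.table modifyList
NULL

VALID_BASES <- c("A", "C", "G", "T", "N")

## known diplonemid mitochondrial gene inventory: 12 assigned genes plus the
## six highly divergent y genes; rnl/rns are the two mitoribosomal RNAs.
KNOWN_GENES <- c("atp6", "cob", "cox1", "cox2", "cox3", "nad1", "nad4",
                 "nad5", "nad7", "nad8", "rnl", "rns",
                 paste0("y", 1:6))
KNOWN_RRNA <- c("rnl", "rns")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a contig record
#'
#' A contig is a genomic sequence (typically one circular mitochondrial
#' chromosome, or a partial assembly thereof) with an optional per-base
#' read-coverage vector.
#'
#' @param id Character scalar identifier.
#' @param seq Nucleotide string over A/C/G/T/N.
#' @param circular Logical; is the molecule circular?
#' @param coverage Optional numeric vector, one non-negative value per base.
#' @return An object of class `mm_contig`.
#' @export
contig <- function(id, seq, circular = FALSE, coverage = NULL) {
  seq <- toupper(seq)
  stopifnot(is.character(id), length(id) == 1L, nchar(seq) >= 1L)
  check_alphabet(seq)
  if (!is.null(coverage)) {
    stopifnot(length(coverage) == nchar(seq), all(coverage >= 0))
  }
  structure(list(id = id, seq = seq, circular = isTRUE(circular),
                 coverage = coverage),
            class = "mm_contig")
}

check_alphabet <- function(seq) {
  bad <- gsub("[ACGTN]", "", seq)
  if (any(nzchar(bad)))
    stop("sequence contains characters outside {A,C,G,T,N}: ",
         paste(unique(strsplit(paste(bad, collapse = ""), "")[[1]]),
               collapse = ""))
  invisible(TRUE)
}

#' Construct a genomic interval
#'
#' Coordinates are 0-based half-open throughout the package; on circular
#' contigs `end` may exceed the contig length by less than one full length,
#' meaning the interval wraps across the origin.
#'
#' @param contig_id Contig identifier.
#' @param start 0-based inclusive start.
#' @param end Exclusive end, `> start`.
#' @param strand `"+"` or `"-"`.
#' @return An object of class `mm_interval`.
#' @export
interval <- function(contig_id, start, end, strand = "+") {
  stopifnot(start >= 0, end > start, strand %in% c("+", "-"))
  structure(list(contig_id = contig_id, start = as.integer(start),
                 end = as.integer(end), strand = strand),
            class = "mm_interval")
}

#' Canonicalize an interval on a circular contig
#'
#' Reduces `start` modulo the contig length while preserving the interval
#' length; intervals longer than the contig are rejected.
#'
#' @param iv An [interval()].
#' @param contig_len Contig length in bp.
#' @return The canonical `mm_interval`; `$wraps` is `TRUE` when the interval
#'   crosses the origin.
#' @export
normalize_circular_interval <- function(iv, contig_len) {
  len <- iv$end - iv$start
  if (len > contig_len) stop("interval length exceeds contig length")
  s <- iv$start %% contig_len
  out <- interval(iv$contig_id, s, s + len, iv$strand)
  out$wraps <- (s + len) > contig_len
  out
}

#' Extract the sequence of an interval, wrap-aware and strand-aware
#'
#' @param ctg An [contig()] (or plain character sequence).
#' @param iv An [interval()].
#' @return The 5'->3' sequence of the interval on its strand.
#' @export
extract_interval <- function(ctg, iv) {
  seq <- if (inherits(ctg, "mm_contig")) ctg$seq else ctg
  L <- nchar(seq)
  iv <- normalize_circular_interval(iv, L)
  s <- if (iv$wraps) {
    paste0(substr(seq, iv$start + 1L, L),
           substr(seq, 1L, iv$end - L))
  } else {
    substr(seq, iv$start + 1L, iv$end)
  }
  if (iv$strand == "-") s <- reverse_complement(s) else s
}

#' Reverse complement
#'
#' Watson-Crick complement, reversed; an involution on its alphabet.
#'
#' @param seq Nucleotide string over A/C/G/T/N.
#' @return Character string.
#' @export
reverse_complement <- function(seq) {
  check_alphabet(toupper(seq))
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(seq))))
}

#' Translate a nucleotide sequence
#'
#' Codon-wise translation from position 0; a trailing partial codon is
#' dropped and ambiguous codons give `X`.  The genetic code actually used by
#' diplonemid mitochondria is not settled; both the standard code and the
#' mold/protozoan mitochondrial code (NCBI table 4, `TGA` = Trp) are exposed.
#'
#' @param seq Nucleotide string, length >= 3.
#' @param code `"standard"` (NCBI table 1) or `"protozoan_mito"` (table 4).
#' @return Amino-acid string in one-letter code (`*` = stop).
#' @export
translate_seq <- function(seq, code = c("standard", "protozoan_mito")) {
  code <- match.arg(code)
  seq <- toupper(seq)
  stopifnot(nchar(seq) >= 3L)
  seq <- substr(seq, 1L, nchar(seq) - nchar(seq) %% 3L)
  gc <- Biostrings::getGeneticCode(if (code == "standard") "1" else "4")
  as.character(Biostrings::translate(Biostrings::DNAString(seq),
                                     genetic.code = gc,
                                     if.fuzzy.codon = "X"))
}

#' Construct a gene model
#'
#' @param name Gene name (conventionally one of the diplonemid mitochondrial
#'   genes `atp6 ... nad8`, `rnl`, `rns`, `y1..y6`, or user-defined).
#' @param kind `"protein"` or `"rRNA"`; defaults from the known inventory.
#' @param module_count Number of genomic modules the gene is split into.
#' @return An object of class `mm_gene_model`.
#' @export
gene_model <- function(name, kind = NULL, module_count = 1L) {
  if (is.null(kind)) kind <- if (name %in% KNOWN_RRNA) "rRNA" else "protein"
  stopifnot(kind %in% c("protein", "rRNA"), module_count >= 1L)
  structure(list(name = name, kind = kind,
                 module_count = as.integer(module_count)),
            class = "mm_gene_model")
}

#' Module table constructor
#'
#' Modules are the separately transcribed genomic gene fragments.  The table
#' keeps, per module, its gene, ordinal (m1 = 1, in 5'->3' mature-transcript
#' order), genomic location, reading-frame offset (`NA` for rRNA) and, when
#' known, its coordinates on the mature transcript.
#'
#' @param gene,ordinal,contig_id,start,end,strand,frame_offset,tstart,tend
#'   Parallel vectors; coordinates 0-based half-open.
#' @return A `data.frame` with class `mm_modules`.
#' @export
module_table <- function(gene = character(), ordinal = integer(),
                         contig_id = character(), start = integer(),
                         end = integer(), strand = character(),
                         frame_offset = integer(), tstart = integer(),
                         tend = integer()) {
  df <- data.frame(gene = gene, ordinal = as.integer(ordinal),
                   contig_id = contig_id, start = as.integer(start),
                   end = as.integer(end), strand = strand,
                   frame_offset = as.integer(frame_offset),
                   tstart = as.integer(tstart), tend = as.integer(tend),
                   stringsAsFactors = FALSE)
  class(df) <- c("mm_modules", "data.frame")
  df
}

#' Genomic sequence of one module row, transcript sense
#' @param mods A module table row (or table plus index `i`).
#' @param contigs Named list of [contig()] objects.
#' @param i Row index.
#' @return Character sequence, 5'->3' in the mature transcript sense.
#' @export
module_seq <- function(mods, contigs, i = 1L) {
  r <- mods[i, ]
  extract_interval(contigs[[r$contig_id]],
                   interval(r$contig_id, r$start, r$end, r$strand))
}

## transcript-sense genomic context immediately downstream (after the 3' end)
## or upstream (before the 5' start) of a module, wrap-aware.
module_context <- function(mods, contigs, i, side = c("down", "up"), len = 12L) {
  side <- match.arg(side)
  r <- mods[i, ]
  ctg <- contigs[[r$contig_id]]
  L <- nchar(ctg$seq)
  fwd <- (r$strand == "+") == (side == "down")
  if (fwd) {
    s <- r$end %% L
    iv <- interval(r$contig_id, s, s + len, "+")
  } else {
    s <- (r$start - len) %% L
    iv <- interval(r$contig_id, s, s + len, "+")
  }
  sq <- extract_interval(ctg, iv)
  if (r$strand == "-") sq <- reverse_complement(sq)
  sq
}

## split a string into single characters
chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

## editing-aware column match in cDNA sense: DNA A may read as RNA G (A-to-I),
## DNA C may read as RNA T (C-to-U); directionality matters.
edit_aware_match <- function(dna, rna) {
  dna == rna | (dna == "A" & rna == "G") | (dna == "C" & rna == "T")
}

random_dna <- function(n, gc = 0.35) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}
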