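Package: mitomosaic
Title: Fragmented Multipartite Mitochondrial Genomes: Simulation, Transcript
    Reconstruction, Module Annotation and RNA-Editing Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the systematically fragmented mitochondrial genomes of
    diplonemid flagellates, in which genes are split into short modules
    dispersed over dozens of circular chromosomes and matured by RNA-level
    trans-splicing and editing. Provides a forward simulator of
    diplonemid-style genomes and transcriptomes with complete ground truth; an
    overlap-layout-consensus reconstructor of mature trans-spliced transcripts
    from partial fragment pools; transcript-to-genome module annotation with
    junction inference, nested-module detection and trans-splicing error
    classification; chromosome classification by recurrent cassette-flanking
    motifs with cassette delimitation and chimera splitting; detection of
    3' uridine-appendage tracts and A-to-I / C-to-U substitution editing with
    SNP subtraction; and cross-species breakpoint, fusion/fission and shared
    editing comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
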