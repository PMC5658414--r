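---
title: "Methods: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The system being modelled

Diplonemid flagellates carry a mitochondrial genome fragmented to an extreme
degree: each gene is split into short pieces (modules, roughly 40–550 nt),
and the modules are dispersed over dozens of small circular chromosomes.
Each chromosome consists mostly of a *constant region* shared with the other
members of its *class*, plus a unique *cassette* that carries one or — in
some species — up to about six modules spaced by ~100 bp. Gene expression
requires transcribing every module separately, joining the module
transcripts in the correct order by trans-splicing, and restoring missing
coding information by RNA editing: non-templated 3' uridine tracts of up to
~50 nt (U-appendage) and clustered deamination edits (A-to-I, read as G in
cDNA, and C-to-U). Some modules are *dual purpose*: a shorter module lies
entirely inside a longer module of another gene, on the same strand and in
the same reading frame, so two different mRNAs share a stretch of identical
protein sequence (up to 22 amino acids for a 66-bp in-frame overlap).

`mitomosaic` implements the full inference chain for this system —
transcript reconstruction from partial fragments, module annotation with
junction inference, chromosome classification, editing detection, and
cross-species breakpoint comparison — together with a forward simulator
that generates genomes and transcriptomes of this architecture with
complete ground truth, so that every stage can be scored without any
external data.

## The forward simulator

`simulate_dataset()` draws mature transcripts first and derives the genome
from them. Per gene: module core lengths are drawn by `plan_fragmentation()`
(uniform composition within 40–550 nt); U-appendage tracts are attached to
a configurable fraction of module 3' ends (default rate 0.25, lengths
1–50 nt); substitution-editing clusters (2–8 sites within a ~30 nt window)
are placed near junctions, mirroring the observed clustering; rare
bi-allelic SNPs are placed inside module interiors (default 0.15% per
coding bp, within the reported 0.05–0.25% range), and the transcript
carries the second allele at those positions. The genomic module copy is
then the *unedited* sequence: tract removed, G→A and C→U reverted, SNP
allele 1 restored. Protein-coding transcripts are kept free of in-frame
stop codons.

Chromosomes are built per class from a shared constant region (default
3.8–8.5 kbp, giving ~4–10 kbp molecules) with 150-bp flanking motifs kept
intact and 1% per-copy divergence elsewhere; cassettes are inserted at one
(or, for bi-cassette classes, two opposed) insertion points. Presets bundle
the two architectures used throughout: `preset_dpap()` (two classes, one
module per cassette, one cassette per chromosome) and `preset_damb()`
(three classes, multi-module cassettes up to six modules ~100 bp apart, a
bi-cassette class, unclassified module arrays, ~94-bp orphan cassettes, and
nested module pairs).

Fragment pools emulate partial transcriptome assemblies: overlapping
fragments (default 200–800 nt, 10× depth, consecutive overlaps ≥ 60 nt), a
configurable fraction carrying unprocessed genomic module flanks at ends
snapped to junctions, poly(A) tails on mRNA 3'-terminal fragments, and
low-rate injected trans-splicing errors of the four canonical types
(over/under-trimming; U addition at a non-editing junction; untrimmed 3'
end instead of a tract; mis-joining of non-cognate modules).

Design choices worth stating explicitly:

* **Truth uses the same junction convention as the annotator** (below).
  After genome assembly the generative module boundaries are canonicalized:
  the upstream module absorbs every following genomic base that continues
  to encode the transcript, and at U-tract junctions genomic Ts on either
  side absorb tract uridines. Ground truth junction positions, tract
  lengths and ambiguity widths are recorded in canonical form, which is the
  only form recoverable from sequence.
* **Editing and SNP clearance.** Editing sites are kept ≥ 16 nt and SNPs
  ≥ 24 nt away from module boundaries. Within a few bases of a boundary,
  substitution editing is not sequence-resolvable (the boundary itself is
  defined by exact genome–transcript agreement), so the generator does not
  create unresolvable truths and the editing caller flags
  boundary-adjacent candidates as uncertain rather than calling them.
* **Nested modules are internal modules.** Dual-purpose nested pairs are
  drawn from internal protein modules of both genes, as in the reported
  cases. A module embedded at a transcript terminus would leave almost no
  flanking disagreement between the two transcripts, making the two layouts
  provably inseparable from fragment evidence alone — a real limitation of
  sequence-level reconstruction, not just of this implementation.
* Gene sequences are random with configurable GC (default 0.35); the real
  genes are not bundled, so tests measure architecture recovery, not
  sequence-specific behaviour.

What the simulator does *not* model: sequencing errors and read-level
coverage (fragments are exact substrings apart from configured noise),
replication/segregation dynamics, within-tract heterogeneity, and
genome-scale base composition structure. Passing round-trip tests therefore
demonstrates correctness of the inference logic under the stated
architecture, not performance on raw sequencing data.

## Transcript reconstruction (overlap–layout–consensus)

Fragments are poly(A)-trimmed (terminal A-runs ≥ 5), then all pairwise
overlaps are computed with a banded Smith–Waterman kernel (match +1,
mismatch −1, gap −2) seeded by shared 16-mers; low-complexity k-mers
(homopolymer and dinucleotide repeats, e.g. poly-U tracts) are excluded
from seeding, and an accepted overlap must contain at least 15 columns
outside its longest homopolymer run — a core dominated by a shared U tract
is not evidence of common origin. Overlaps must reach `min_overlap` (20 nt)
at `min_identity` (0.98), with up to `max_end_skip` (60 nt) of unaligned
sequence at the fragment ends facing into the overlap: this is the
flank tolerance for unprocessed precursor ends. Placement offsets come from
the modal aligned diagonal, which is robust to stray gaps inside flank
ends.

The layout is a maximum-score spanning forest. Three repair mechanisms
operate on it:

1. overlaps contradicting the forest placement (indel-carrying mis-spliced
   fragments) are dropped, so such a fragment only contributes the side
   corroborated by surviving overlaps;
2. fragment ends that several partners refuse to align through, while
   almost nobody aligns through them, are barred from the consensus
   (unprocessed flank junk);
3. components containing fragments whose placed cores disagree deeply
   (< 55% identity over ≥ 150 columns) are split into camps seeded by the
   incompatible pair: a fragment joins a camp unless it disagrees with a
   member, fragments compatible with both camps (cores confined to a
   dual-purpose shared region) follow their strongest edge, fragments
   disagreeing with both camps (chimeras from mis-joined modules) are
   isolated, and all camp-crossing edges are cut.

Consensus is per-column majority over fragment cores, with ties broken
toward the base of the longest supporting fragment, then alphabetically. A
support-1 run protruding past a well-supported terminus is trimmed.
`iterative_extend()` recovers missing terminal modules by appending the
consensus of fragment protrusions beyond a transcript end until a fixed
point. The default thresholds (20/0.98/60) are package choices exposed in
the configuration; no published values exist for the original pipeline.

## Module annotation and the junction convention

Transcripts are mapped by exact 20-mer seeding plus x-drop extension with
editing-aware scoring: a genomic A may pair with transcript G and a genomic
C with transcript U, in those directions only. Regions whose exact seeds
are destroyed by dense editing clusters are rescued with a second seeding
pass in a deamination-collapsed alphabet (G folded onto A, T onto C);
extension and identity are always computed on the real sequences.

Junctions between chained hits follow one convention everywhere, in the
simulator's canonical truth and in the annotator:

* the upstream module extends as far as its genomic copy continues to
  encode the transcript exactly (*upstream-maximal* attribution; the hit
  end is located from the last long strict-match run, so chance
  editing-tolerant matches cannot displace it);
* at U-appendage junctions the boundary sits downstream of the last
  genome-encoded T, on both sides: genomic Ts trailing the upstream module
  and genomic Ts leading the downstream module absorb tract uridines;
* the residual transcript-only run between modules must be pure U to be
  called a tract; any other gap raises a missing-module diagnostic;
* the recorded ambiguity width is the shared identical run at the
  downstream module start; widths above 6 nt are flagged unresolved
  (beyond the observed range);
* terminal T/A residues follow the genome-encoded convention: poly(A)
  trimming removes runs of ≥ 5 terminal As only, and hit extension absorbs
  genome-encoded terminal bases.

`find_module_overlaps()` reports genomic overlaps between modules of
different genes with strand relation and, for same-strand protein pairs,
frame equality (`floor(overlap_bp/3)` amino acids when in frame).
`classify_junction_errors()` types a fragment against the expected
transcripts with priority iv > iii > ii > i when signatures co-occur; the
priority order is a package decision, the four types are as described for
imprecise trans-splicing.

## Chromosome classification

Cassette-flanking motifs are maximal shared blocks (> 100 bp at > 90%
identity, both thresholds strict) in the 2-kbp windows flanking each module
array, grouped by representative-based clustering; contigs sharing the same
motif pair (or pair of pairs, for bi-cassette chromosomes) form a class,
labelled A, B, C … by descending member count. A contig combining motifs
of two classes is flagged as a hybrid chromosome. Identity is computed over
alignment columns with gaps counting as mismatches; whether the original
90%/100 bp rule was gap-compressed is not stated anywhere, so this
convention is declared, not claimed identical.

Cassette boundaries come from a center-star comparison of class members:
per-base match profiles against a center member, smoothed with a trailing
100-bp mean; a maximal run below 0.90 is one cassette, refined to the
unmatched run inside the candidate span. Chimeric mito/nuclear contigs are
split at the maximal coverage step between a ≥ 200× and a < 100× segment,
the reported coverage regimes of validated mitochondrial versus nuclear
contigs.

## Editing detection and statistics

Per annotated module the transcript segment is paired gaplessly with its
genomic copy (the only tolerated length difference is the trailing RNA-only
tract; any other indel is rejected, mirroring the discarded-indel rule of
read-based calling). DNA A / RNA G columns are called A-to-I, DNA C / RNA U
columns C-to-U; columns matching a supplied bi-allelic SNP are subtracted,
and all other mismatches are reported as rejected columns. Candidate sites
closer than 8 nt to a module boundary are reported separately as uncertain.
Clusters are single-linkage groups with gaps ≤ 20 nt and ≥ 2 sites — the
numeric rule is a package choice (the observation is only that sites are
"densely clustered") and both parameters are exposed.

`u_tract_frame_compensation()` checks that module length plus tract length
differs between species by multiples of 3 for internal protein modules.
`at_equalization()` reports the across-species A+T-content spread as
max − min in percentage points, rounded to integers; whether the published
16%→7% contraction used this dispersion measure is not stated, so
max − min is the declared convention. The genetic code used by diplonemid
mitochondria is unsettled; translation exposes both the standard code and
the protozoan mitochondrial code (table 4) and asserts neither.

## Cross-species comparison

Ortholog alignments are center-star merges of pairwise global alignments
(deterministic for fixed input); junction offsets project to alignment
columns and match within a 6-nt window (the maximal observed junction
ambiguity), with shifts reported in ungapped nt. A junction present in one
species and absent in another, with shared flanking junctions, is a
fusion/fission event; direction labels are relative. Shared editing
compares sites by column and kind, clusters by span overlap.

## Problem sizes and determinism

Every stage is deterministic given the configuration seed. The unit-test
suite runs the generator at a reduced scale (6–8 genes, 1.2–2.5 kbp
chromosomes, ~20–35 modules) to keep runtime low; the acceptance suite
runs the two full-scale presets (18 genes, ~80 modules, ~4–10 kbp
chromosomes, 10 seeds each) through the complete pipeline, which takes on
the order of 15 s per dataset on one CPU. Exactness claims (byte-identical
transcripts, exact module boundaries, junctions and editing events,
classification ARI of 1) are made for error-free fragment pools; with 0.5%
fragment substitution noise, at least 95% of junctions remain exact, and
the four trans-splicing error types are injected and exercised in the
standard presets, where mis-joined fragments must be excluded or flagged.

## Known limitations

* A dual-purpose module embedded at a transcript terminus cannot be
  separated from its host by fragment evidence alone; the generator
  restricts nesting to internal modules and real terminal cases would
  need read-level or poly(A)-anchored evidence.
* Motif discovery compares contigs in their stored orientation; real
  assemblies would first need orientation adjustment.
* Classification assumes chromosomes are stored rotated so cassettes do
  not span the sequence origin; the simulator guarantees this, real input
  may need re-rotation.
* The editing caller does not model inosine chemistry or read pileups;
  it subtracts only bi-allelic SNPs, the observed mode.
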