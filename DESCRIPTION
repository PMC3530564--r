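Package: caprimir
Title: Small RNA Sequencing Pipeline for Conserved and Novel miRNA
    Discovery in Two-Library Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of the classic two-library small
    RNA sequencing workflow used for miRNA discovery in livestock
    transcriptomics: adapter and quality filtering with Table-style read
    accounting, collapsing to unique tags, one-mismatch genome mapping,
    hierarchical annotation against non-coding RNA and genomic feature
    classes, conserved miRNA quantification against a miRBase-flavour
    reference with arm assignment, novel hairpin prediction by
    minimum-free-energy folding under a simplified nearest-neighbour
    model and a seven-criteria stem-loop filter, exact two-library
    differential expression (Audic-Claverie), and stem-loop qPCR
    quantification by the Livak 2^-ddCt method.  Ships a synthetic-data
    generator with a ground-truth manifest so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rcpp,
    rtracklayer,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
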