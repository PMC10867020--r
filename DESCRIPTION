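Package: stemsig
Title: Leukemic Stem Cell and Blast Signature Analysis for t(8;21) AML
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving leukemic stem cell (LSC) and blast gene
    expression signatures from bulk RNA-seq, classifying single-cell
    RNA-seq clusters against those signatures with a preranked gene set
    enrichment (GSEA) statistic, quantifying differential chromatin
    accessibility over peak unions, scoring transcription-factor motif
    enrichment across peak sets, and summarising mass cytometry (CyTOF)
    population statistics. Includes seeded synthetic-data generators that
    emulate the statistical structure of the corresponding assays so the
    whole workflow is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils,
    methods,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea
Config/testthat/edition: 3
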