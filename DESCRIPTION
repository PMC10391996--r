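Package: fibergrn
Title: Chromatin Accessibility Dynamics and Transcription Factor Regulatory
    Networks for Staged Ovule and Fiber Development
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end cis-trans regulatory analysis toolkit for
    multi-stage chromatin accessibility (DNase-seq style DHS intervals) and
    expression count data: DHS genomic annotation and transposable-element
    derived DHS (teDHS) classification, replicate quality control with
    pseudo-replicate rescue ratios, size-factor normalization and a
    simplified negative-binomial Wald test for differential accessibility
    and expression, empirical-null peak-to-gene linking with a z-score test,
    position-weight-matrix motif scanning with exact score p-values and
    hypergeometric enrichment, mutual-rank gene co-expression networks,
    joint k-means profile clustering, and construction of a merged
    transcription-factor regulatory network. Includes a fully ground-truthed
    synthetic data generator emulating a six-stage ovule/fiber design for
    validation of every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    withr,
    jsonlite,
    yaml,
    igraph,
    BiocGenerics,
    S4Vectors,
    GenomeInfoDb,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
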