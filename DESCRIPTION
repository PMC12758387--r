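Package: guttag
Title: Single-Cell CUT&Tag Analysis of Repressive Chromatin in the Aging Fly Gut
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for analysing single-cell and bulk CUT&Tag
    fragment data from the Drosophila midgut across ages. Provides fragment
    reading and coverage tracks, sparse-enrichment calling of broad H3K27me3
    domains by signal-block AUC thresholding, per-cell quality control
    (fragment count, FRiP, blacklist fraction) and synthetic-doublet scoring,
    TF-IDF/LSI embedding with shared-nearest-neighbour Leiden clustering,
    chromatin silencing scores for marker-based cell typing, pseudobulk
    negative-binomial differential testing of genes and enhancers within
    domains, FIMO-style position-weight-matrix scanning with exact dynamic
    programming p-values, bulk RNAPII-S5P promoter statistics including a
    difference-versus-average hypertranscription plot and an exact Poisson
    rate test, and Monte Carlo permutation testing of cell-type composition.
    Ships a synthetic fragment generator with planted ground truth so every
    stage of the pipeline can be validated by recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    Matrix,
    igraph,
    irlba,
    uwot,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
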