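Package: modclust
Title: Iterative Gene-Module Clustering for Plate-Based Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cell-type discovery for deep plate-based single-cell RNA-seq of
    sorted neuron populations. Implements cell-level quality control (gene
    detection and glial/satellite-cell contamination filters) with CPM
    normalization, Fano-factor gene selection, WGCNA-style co-expression gene
    modules with a permutation significance test, recursive eigengene-space
    Ward clustering with a moderated-t merge criterion, bootstrapped
    co-clustering consensus, pairwise differential expression with binary
    on/off marker selection, classic and elim Fisher gene-set enrichment, and
    longitudinal gene-gene correlation panels across developmental stages.
    Ships a negative-binomial count simulator with fully planted ground truth
    so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    limma,
    Rtsne,
    fgsea,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
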