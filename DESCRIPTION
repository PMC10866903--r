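Package: scInflamed
Title: Discovery and Pharmacogenomic Characterization of Inflamed Tumor-Cell
    States from Single-Cell RNA-seq
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for discovering transcriptionally distinct tumor-cell
    subpopulations in single-cell RNA-seq data and characterizing a rare
    interferon-stimulated-gene (ISG) "inflamed" state. Provides quality-control
    filtering, log-normalization, variance-stabilizing selection of highly
    variable genes, covariate regression, PCA with jackstraw selection of
    significant components, silhouette-optimal K-means (or Louvain) clustering
    with Wilcoxon marker tests, gene-module scoring against expression-matched
    control genes, expression-based copy-number inference by chromosome-ordered
    moving averages with subclone clustering, pharmacogenomic correlation
    screening of module scores against drug-response panels (with IC50 and
    growth-rate-inhibition dose-response metrics), paired pre/post-treatment
    enrichment statistics, and Kaplan-Meier/log-rank survival analysis of
    signature strata. A negative-binomial synthetic-data generator with planted
    ground truth emulates every input for testing and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    survival,
    cluster,
    irlba,
    igraph,
    ape,
    minpack.lm,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    fgsea,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
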