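Package: bhotmodel
Title: Classification and Heterogeneity Modelling of Kidney Allograft
    Expression on the Banff Human Organ Transplant Panel
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating the Banff Human Organ Transplant (BHOT)
    gene panel as a microarray surrogate for kidney-allograft diagnosis.
    Provides a seeded generator of synthetic log2 expression cohorts with
    planted diagnostic module shifts, within-class subtype heterogeneity,
    batch effects and housekeeping genes; ingest of expression matrices
    (TSV or GEO series-matrix) with panel subsetting, housekeeping
    renormalization and coefficient-of-variation screening; batch detection
    on low-CV genes via UMAP embedding and scalar batch correction; three
    principal-component parsing strategies (supervised contrast-based,
    gene-set based, and unsupervised) with robust standardization and
    eigenvalue retention; a registry of cross-validated classifiers with
    confusion-matrix, ROC and log-loss reports and per-sample discordance
    analysis; K-means cluster-number selection by Sarle's cubic clustering
    criterion; per-diagnosis distribution summaries with Hartigan's dip
    test; and a discretized tree-augmented naive Bayes model with
    MDL-pruned structure, Bayes factors and exact inference.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    limma,
    fgsea,
    uwot,
    cluster,
    glmnet,
    ranger,
    xgboost,
    mixOmics,
    MASS,
    matrixStats,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pROC,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
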