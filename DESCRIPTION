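Package: coexPath
Title: Co-Expressed Pathway Prediction from Gene Expression Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Ranks pathways for every gene of an expression compendium by the
    co-expression of their member genes. Builds a gene-gene Pearson
    correlation matrix from a quantile-normalized, log-transformed expression
    matrix; performs multi-threshold over-representation analysis (one-sided
    Fisher's exact test) on the top co-expressed genes; runs unweighted gene
    set enrichment analysis on each gene's full ranked list with exact
    gene-permutation p-values computed by lattice-path dynamic programming;
    and calibrates enrichment scores into percentile (p-)scores via a
    Gaussian kernel density model of each pathway's observed score
    distribution, which removes the inflation caused by internal correlation
    within pathways. Includes diagnostics for that inflation, ROC/AUC
    evaluation of gene-pathway predictions, and a seeded generator of
    synthetic expression matrices with planted co-expressed pathways.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    SummarizedExperiment,
    S4Vectors,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
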