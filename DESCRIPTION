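Package: cellspin
Title: BackSPIN Biclustering and Downstream Analysis of Single-Cell UMI Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested reimplementation of a single-cell RNA-seq analysis
    pipeline for developing ventral midbrain data: quality control of UMI
    count matrices, coefficient-of-variation feature selection against an
    SVR noise model, SPIN sorting of correlation matrices and recursive
    BackSPIN biclustering of cells and genes, a Bayesian negative-binomial
    generalized linear model for marker discovery with posterior-probability
    binarization, cross-species cell-type matching by mutual best
    correlation over one-to-one homologs, a learned cell-cycle proliferation
    index, principal-curve pseudotime with smooth expression profiles and
    affinity-propagation profile clustering, and a multinomial prototype
    classifier with a probability-simplex "wheel" embedding. Includes a
    synthetic-data generator emulating the statistical structure every stage
    assumes, so the whole pipeline is reproducible without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    MASS,
    e1071,
    glmnet,
    jsonlite,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
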