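Package: emospace
Title: Dimensional Analysis of Emotion-Experience Rating Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for the dimensional analysis of emotion-experience
    rating studies in which participants rate evoked (narrative, video) or
    real-life emotion episodes on bounded 1-7 scales. Covers scale-quality
    screening (test-retest and split-half reliability, readability),
    representational similarity analysis with permutation tests, factor
    retention (parallel analysis, optimal coordinate, acceleration factor,
    VSS, Velicer's MAP, empirical BIC, and EFA-to-CFA cross-validation),
    exploratory factor analysis (minres extraction, oblimin rotation,
    ten Berge scores) with decimation robustness checks and Tucker/Procrustes
    factor congruence, principal preserved component analysis with a
    split-half leave-one-out significance procedure, two-dimensional manifold
    embedding with cross-validated neighborhood-size selection, cluster and
    unimodality analysis (Ward clustering, K-means recovery scoring,
    Hartigan's dip test), maximum-variation stimulus sampling, and an
    individual-differences association screen. A synthetic-data generator
    with a known latent factor structure provides a recoverable ground truth
    for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    uwot
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    boot,
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
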