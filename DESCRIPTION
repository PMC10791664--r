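Package: omstnet
Title: Graph-Theoretical Analysis of Functional Connectomes and General
    Intelligence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds edge-weighted functional connectivity networks from
    regional time series (pairwise partial correlations controlling
    confound series, negative clipping, Fisher z-transform), prunes them
    with data-driven orthogonal minimum spanning trees (OMST) maximizing
    global cost efficiency, computes weighted graph metrics (global and
    nodal efficiency, global and local clustering, small-world propensity
    with lattice and random nulls), and runs the association battery
    linking the metrics to a general-intelligence factor: winsorization,
    covariate residualization, Holm-corrected partial correlations,
    elastic-net selection of nodal predictors, cross-sample prediction
    with Bonferroni correction, predictor-set overlap, ICC(3,1)
    test-retest reliability and Spearman-Brown split-half reliability.
    A synthetic-cohort generator produces BOLD-like multi-subject data
    with planted effects so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    Matrix,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    igraph,
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
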