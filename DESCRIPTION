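Package: tegs
Title: Variance Component Tests for the Effect of a Gene Set
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests whether a phenotype or exposure is associated with the joint
    expression profile of a gene set, using a variance component score test on a
    multivariate linear model in which the correlation among genes is modelled
    through a working covariance matrix (TEGS). Provides a menu of working
    covariance estimators (independence, ridge-stabilized unstructured, compound
    symmetry, two-factor and adaptive factor analysis), permutation,
    Satterthwaite scaled chi-square and normal-mixture null approximations,
    Storey q-value adjustment across gene sets, analytic power calculations for
    the quadratic-form statistic, readers for GCT/CLS/GMT/TSV inputs, and a
    simulation harness for size and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
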