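Package: fersigr
Title: Ferroptosis-Associated Molecular Subtyping and Fersig Scoring for
    Colorectal Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Consensus non-negative matrix factorization (NMF) subtyping of
    bulk tumor expression profiles restricted to a ferroptosis gene list,
    single-sample gene set enrichment (ssGSEA) scoring of microenvironment
    and pathway signatures, derivation of immune-activated and
    stromal-activated ferroptosis signatures from one-vs-rest differential
    expression, a PCA-based per-patient Fersig score composed by the sign of
    univariate Cox coefficients, and projection of the bulk subtypes onto
    single cells through binned-control module scores. Ships a synthetic
    cohort generator (bulk, single-cell and immunotherapy cohorts with
    ground truth) so the whole pipeline can be exercised and validated
    end to end without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    Rcpp,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
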