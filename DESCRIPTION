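Package: clogitforest
Title: Conditional Logistic Regression Forests for Matched Case-Control Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Random forests whose base learners are conditional logistic
    regression trees, for the analysis of 1:m matched case-control studies.
    Provides ridge-penalized conditional logistic regression (CLR), likelihood
    guided recursive partitioning embedded in the CLR framework with optional
    BIC pruning, stratum-level bagging with mtry decorrelation and an optional
    linear covariate offset, permutation variable importance scored by the
    predictive conditional likelihood, nonparametric bootstrap confidence
    intervals for a dedicated exposure effect, and a synthetic-data generator
    emulating district-matched epidemiological study designs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    parallel,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
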