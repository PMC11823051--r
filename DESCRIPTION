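Package: goaldr
Title: Doubly Robust Dose-Response Estimation for Continuous Treatments
    in High Dimensions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates the causal dose-response function of a continuous
    treatment under high-dimensional covariates.  Covariates are selected
    by an outcome-model-free adaptive lasso on the treatment model whose
    penalty weights derive from kernel-smoothed conditional distance
    correlations with the outcome; balance weights are distance-covariance
    optimal weights (DCOWs) obtained from a convex quadratic program; the
    lasso tuning parameter is chosen by minimizing a dual-weight distance
    correlation (DWDC) criterion; and the dose-response function is
    estimated by regressing a doubly robust pseudo-outcome on the
    treatment.  Includes the SL-DR density-ratio comparator, analytic and
    bootstrap standard errors, and a Monte-Carlo simulation harness with
    the usual bias / empirical SD / coverage / power / RMSE summaries.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    glmnet,
    xgboost,
    randomForest,
    e1071,
    pracma,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
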