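Package: mlmisim
Title: Simulation Study of Multiple Imputation Methods for Multilevel Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to run a Monte Carlo simulation study comparing
    parametric and tree-based multiple imputation for two-level
    (clustered) data. Generates balanced hierarchical datasets with
    clustered predictors and random-intercept or random-slope outcomes,
    induces MCAR and binned-MAR missingness at level 1 and cluster-level
    MCAR at level 2, imputes with fully conditional specification using
    a Bayesian two-level normal model, cluster-level predictive mean
    matching, chained random forests, and gradient boosting (each tree
    method optionally augmented with cluster-membership dummy
    variables), analyzes completed data with linear mixed models, pools
    with Rubin's rules, and scores type I error, power, bias, standard
    deviation ratios, and standard error calibration with Monte Carlo
    standard errors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    ranger,
    xgboost,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), lmerTest, withr, knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
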