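Package: confsol
Title: Conformal Prediction Intervals for Boosted-Tree Solubility Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Builds informative aqueous/organic solubility estimates, Log(S),
    from molecular-descriptor tables using gradient-boosted tree regression
    with forward-stepwise top-importance (FSTI) variable selection, a
    k-nearest-neighbour applicability-domain gate, and a family of
    cross-conformal predictors (AR, ARS, ARSS, error-model, kNN-distance)
    that attach per-compound prediction intervals at several confidence
    levels.  Includes statistical validation of interval error rates,
    efficiency comparison against the constant-width baseline, accuracy-class
    assignment for screening sets without experimental solubilities, and a
    seeded synthetic-data generator for method checks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
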