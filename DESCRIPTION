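Package: ensdm
Title: Ensemble Species Distribution Modelling with Field Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for presence-background species
    distribution modelling of narrow-range species on high-resolution terrain.
    Derives terrain covariates (slope, northness, eastness), geology proximity
    classes and a soil colour index from gridded inputs; engineers presence,
    background and true-absence point sets with spatial thinning and exclusion
    rules; fits a suite of suitability models (downsampled and shallow random
    forests, boosted regression trees, a regularized presence-background
    logistic model, multivariate adaptive regression splines and generalized
    additive models) behind one uniform contract; combines them into an
    AUC-PR-weighted ensemble; converts continuous suitability into binary
    habitat maps at a fixed sensitivity; and evaluates predictions against
    field-survey cells with rank-sum tests, Cliff's delta and contingency
    statistics. A synthetic-landscape generator with a known logistic
    suitability truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv,
    glmnet,
    randomForest,
    ranger,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
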