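Package: soyield
Title: County-Level Soybean Yield Estimation with a GOA-Tuned CNN-BiGRU-Attention Network
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Estimates county-level soybean yield from monthly multi-source
    remote-sensing predictors (surface reflectance and vegetation indices,
    environmental variables, and photosynthesis-related parameters). Implements
    a CNN-BiGRU regression network with additive attention pooling, trained
    with Huber loss and Adam, whose hyperparameters can be tuned by a
    from-scratch Grasshopper Optimization Algorithm; five comparison models
    (support-vector regression, random-forest regression, CNN, GRU, CNN-GRU);
    the standard regression metrics R2, RMSE, MAE and MAPE; a temporal
    train/test protocol; a variable-group ablation harness; sampled-Shapley
    per-variable importance; and a calibrated synthetic-data generator that
    reproduces published variable-yield correlation structure so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    e1071,
    randomForest,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
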