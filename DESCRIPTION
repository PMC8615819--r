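Package: hoconn
Title: Low- and High-Order Functional Connectome Predictive Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constructs low-order (Pearson) and high-order
    ("correlation of the correlation") functional connectomes from
    region-wise time series, selects predictive network edges with
    randomized-LASSO stability selection, fits linear and linear-kernel
    support-vector regression models of a continuous behavioural score
    under nested leave-one-out cross-validation with majority-voted
    hyperparameters, and builds a consensus final model with named
    network edges. Includes a synthetic-cohort generator with planted
    edge-level signal for validating the pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    kernlab,
    MASS,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
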