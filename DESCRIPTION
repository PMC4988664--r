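Package: disurv
Title: Classical and Discrete-Time Survival Analysis with Neural-Network
    Hazard Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Survival analysis toolkit for right-censored clinical data:
    Kaplan-Meier estimation with Greenwood confidence bands, median survival
    and reverse Kaplan-Meier median follow-up, weighted log-rank family
    curve-comparison tests (log-rank, Peto-Peto, Tarone-Ware), kernel-smoothed
    hazard rate estimation with Epanechnikov and Gasser-Mueller boundary
    kernels, Cox proportional-hazards regression with Breslow, Efron and exact
    tie handling plus stepwise selection and proportional-hazards diagnostics,
    contingency-table analysis, and a discrete-time individual survival
    predictor based on a single-hidden-layer neural network trained on
    per-interval hazard targets with cross-validated hidden-layer-size
    selection.  Includes a synthetic-cohort generator with known discrete
    hazards for validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    survival,
    MASS,
    nnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
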