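Package: cfvalid
Title: Counterfactual Validation of Predictions Under Interventions for
    Time-to-Event Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Evaluates the counterfactual predictive performance of
    prediction-under-interventions models for time-to-event outcomes using
    longitudinal observational validation data. Follow-up is artificially
    censored when a subject deviates from the static treatment strategy under
    which predictions were made, and the remaining person-time is reweighted
    by inverse-probability-of-artificial-censoring weights estimated from
    pooled logistic treatment models. Provides counterfactual analogues of
    mean and grouped calibration (weighted Kaplan-Meier observed risk,
    observed/expected ratio), discrimination (truncated c-index and
    cumulative/dynamic AUC at a horizon) and overall prediction error (Brier
    score and scaled Brier score), together with the naive subset-approach
    comparator and a simulation framework that generates confounded
    longitudinal data with matched perfect counterfactual validation sets.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    survival,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
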