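Package: sepsiskit
Title: Clinical Utility Scoring, Sepsis-3 Labeling, and Synthetic ICU Cohorts
    for Hourly Sepsis Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for evaluating hourly sepsis-prediction algorithms on ICU
    time series. Implements the time-dependent clinical utility score that
    rewards early sepsis predictions and penalizes late or missed predictions
    and false alarms, with normalization against optimal and inaction
    reference predictors; a Sepsis-3 onset labeler (suspicion of infection
    from antibiotic/culture timing, SOFA two-point rise, and their
    reconciliation into an onset time); readers and writers for the
    pipe-separated hourly patient-record format with cohort inclusion and
    truncation rules; a seeded generator of synthetic multi-hospital ICU
    cohorts with hourly vitals, sparse daily laboratories, planted sepsis
    onsets, and inter-hospital distribution shift quantified by
    Jensen-Shannon divergence; and a Weibull proportional-hazards baseline
    predictor producing hourly risks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    pROC,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
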