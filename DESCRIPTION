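Package: tvmatch
Title: Time-Varying Risk-Set Matching and Survival Analysis for
    Hospitalized-Cohort Studies
Version: 0.1.0
Authors@R:
    person("CSAPG", "Analytics", email = "analytics@example.org",
           role = c("aut", "cre"))
Description: Tools for observational treatment-effect analyses in
    hospitalized cohorts with longitudinal daily observations. Implements
    brute-force risk-set matching with time-varying covariates (hard
    clinical windows on oxygenation, inflammation and radiology, followed
    by propensity-score refinement and 1:1 pairing without replacement),
    matched-cohort balance diagnostics, Kaplan-Meier/log-rank time to
    discharge, adjusted Cox proportional-hazards models on unmatched
    subcohorts, and a synthetic longitudinal cohort generator with
    severity-confounded treatment assignment and a configurable true
    treatment effect for validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    glmnet,
    jsonlite,
    stats,
    survival,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
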