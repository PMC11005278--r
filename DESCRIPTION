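Package: addinter
Title: Additive-Scale Interaction Analysis for Weighted Epidemiologic Cohorts
Version: 1.0.0
Authors@R: person("Addinter", "Developers", email = "addinter@example.org",
    role = c("aut", "cre"))
Description: Tools to assess additive-scale interaction between two binary
    exposures on a binary outcome in survey-weighted cohort data. Provides a
    synthetic cohort generator with known ground truth (correlated binary
    exposures, categorical confounders, sampling weights, injected
    missingness), a complete-case exclusion flow and variable recoding, a
    survey-weighted logistic regression fitter with model-based and sandwich
    (optionally cluster-robust) covariance, the relative excess risk due to
    interaction (RERI), attributable proportion (AP) and synergy index (S)
    with delta-method and bootstrap confidence intervals, and a
    configuration-driven pipeline that renders study-style report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
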