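Package: scanwear
Title: Engagement, Retention and Scan-Proximity Physiology in Wearable
    Digital-Health Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for longitudinal digital-health studies in
    hereditary-cancer surveillance cohorts. Provides a synthetic cohort
    generator with planted ground truth; daily engagement metrics with
    Welch-corrected group comparisons; an active/inactive/exit day-state
    machine feeding Kaplan-Meier retention analysis and log-rank tests;
    FFT periodograms of smoothed adherence series with dominant-period
    extraction; per-scan-event generalized additive models linking
    minute-level wearable physiology (electrodermal activity, heart rate,
    heart-rate variability, respiratory rate, skin temperature) to scan
    proximity, with chained-equation imputation, cross-validated error and
    partial-dependence similarity; and questionnaire scoring (PHQ-9, GAD-7,
    PSS-4, PROMIS Sleep-Related Impairment) with a PHQ-9 item-9 self-harm
    alert audit.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    mgcv,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
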