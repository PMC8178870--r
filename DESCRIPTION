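Package: accelmi
Title: Missing-Data Framework for Accelerometer Step-Count Outcomes in Trials
Version: 0.1.0
Authors@R:
    person("Mia", "Whitfield", email = "mia.whitfield@example.org",
           role = c("aut", "cre"))
Description: Tools for handling missing daily step-count outcomes in
    randomized trials that measure physical activity with accelerometers
    over repeated 7-day periods. Days are classified as observed, partially
    observed (right-censored) or missing from device wear time; missing and
    partial days can optionally be replaced by same-weekday records from the
    following week; daily log step counts are multiply imputed by chained
    equations with interval-censored (Tobit) Gaussian regression, separately
    by treatment arm, under missing-at-random or delta-adjusted
    missing-not-at-random assumptions; and the week-average primary analysis
    is fitted with arm-specific unstructured residual covariance and pooled
    across imputations by Rubin's rules. A synthetic trial generator with
    configurable MCAR/MAR/MNAR wear mechanisms supports simulation studies
    and testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
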