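Package: empcalsim
Title: Simulation Assessment of Empirical Calibration of Confidence Intervals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing how well empirical calibration of 95%
    confidence intervals performs under known sources of bias in
    observational treatment-effect estimation. Generates synthetic cohorts
    with binary treatment, a binary outcome of interest and negative-control
    outcomes under configurable bias mechanisms (unmeasured confounding,
    model misspecification via quadratic or interaction terms, structural
    positivity violations, and covariate measurement error); estimates log
    odds ratios by stabilized inverse-probability-of-treatment-weighted
    logistic regression with model-robust sandwich standard errors;
    synthesizes positive-control outcomes with known target effects by
    coefficient reuse; fits empirical null and systematic-error models by
    maximum likelihood; and evaluates coverage, standardized absolute bias
    and interval width of calibrated versus uncalibrated estimates across
    simulation scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    sandwich,
    optparse
Config/testthat/edition: 3
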