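Package: qrmetric
Title: Quantitative Response Metric for C-Peptide Outcomes in Type 1
    Diabetes Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes the quantitative response (QR) metric for
    disease-modifying-therapy trials in recently diagnosed type 1
    diabetes: a baseline-covariate-adjusted, standardized C-peptide
    outcome defined as the difference between the observed and the
    ANCOVA-predicted ln-transformed 1-year 2-hour C-peptide AUC mean.
    Provides the published QR model, ANCOVA model fitting and
    cross-cohort validation, interim (3/6/9 month) QR, responder
    classification under five definitions with covariate-bias
    diagnostics, arm-level summaries and treatment-effect tests on
    three outcome scales, placebo-percentile mapping and a weighted
    logistic probability-of-effective-therapy curve, and a synthetic
    multi-trial generator for power and interim-decision experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
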