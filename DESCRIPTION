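Package: fpmort
Title: Fractional Polynomial Modelling of the BMI-Mortality Relationship
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multivariable fractional polynomial (MFP) analysis of the
    relationship between body mass index and short-horizon all-cause
    mortality in survey cohorts. Provides fractional polynomial design
    bases with scaling and centering, survey-weighted logistic regression
    by iteratively reweighted least squares, closed-test function
    selection with MFP cycling and backward elimination, interaction
    detection (MFPI) with Lowess-based graphical verification, closed-form
    estimation of the BMI of minimum mortality with delta-method
    confidence intervals, comparison against linear, linear-quadratic,
    and categorical BMI models, and a calibrated synthetic cohort
    generator emulating a pooled US national interview survey linked to
    death records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
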