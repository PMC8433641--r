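Package: siaval
Title: Stability-Indicating Assay Validation and Degradation Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for validating stability-indicating chromatographic
    assays in the style of the ICH Q2(R1) guideline, and for analysing
    chemical degradation kinetics of the quantified analyte.  Covers
    system-suitability summaries (injection repeatability, USP tailing
    factor, theoretical plates, resolution), homoscedasticity testing of
    calibration responses, ordinary and weighted least-squares calibration
    with data-driven selection of the weighting factor (1, 1/x, 1/x^2) by
    the summed absolute percent relative error of back-calculated
    concentrations, lack-of-fit and regression ANOVA diagnostics,
    signal-to-noise based detection and quantitation limits, accuracy and
    precision (percent recovery) evaluation, forced-degradation percent
    remaining bookkeeping, and zero/pseudo-first/second-order rate-law
    fitting with rate-constant and half-life estimation.  A seeded
    synthetic-data generator reproduces the statistical structure of
    chromatographic peak tables so every stage can be exercised without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
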