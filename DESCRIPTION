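Package: gammapodqa
Title: Patient-Specific Quality Assurance for Stereotactic Breast
    Radiosurgery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computational toolkit for patient-specific quality assurance
    (PSQA) of cup-based stereotactic breast radiosurgery delivered as a
    sequence of control points (table position, collimator, dwell time).
    Provides a kernel-superposition forward dose engine built on isocenter
    dose-rate and off-center-ratio tables, a semi-empirical independent
    point-dose calculation (SEIPDC) with an empirically calibrated
    volume-dependence correction factor, QA-plan generation by target-centroid
    shifting, plateau-normalized 3%/1 mm gamma-index analysis, a radiochromic
    film workflow (calibration-curve fitting, rigid four-mark registration,
    synthetic film generation), profile-area sensitivity analytics, and QA
    error-band/classification statistics, together with synthetic plan and
    kernel-table generators for end-to-end validation without proprietary
    vendor data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
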