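Package: nirlib
Title: Spectral-Library Construction of Near-Infrared Quantitative Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds near-infrared (NIR) quantitative calibration models for
    pharmaceutical oral dosage forms from a spectral library. Spectra are
    indexed by their correlation coefficient (r_T) against a reference
    spectrum; calibration samples are selected around the median r_T of the
    samples to be analysed with a fixed r_T spacing; PLS1 content models
    (active ingredient, co-formulated ingredient, water) are fitted with
    PRESS-based F-test rank selection, validated by test-set or leave-one-out
    cross validation, and optimised by transferring poorly predicted test
    spectra into the calibration set. A conventional Ward-clustering
    calibration-set builder and a synthetic spectral-library generator are
    included so the whole workflow is testable without proprietary spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
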