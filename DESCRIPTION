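Package: ctadose
Title: Inverse-Problem Contrast-Media Dose Planning for Head and Neck CT
    Angiography
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-stage pipeline for contrast kinetics in head and neck
    CT angiography. Stage one fits a 29-term semi-empirical regression
    (seven min-max normalized patient and facility risk factors, all 21
    pairwise interactions, and a constant) of the CTA number of the left
    artery by normal-equations least squares. Stage two inverts the
    fitted model per patient to recommend the contrast-media volume that
    drives the predicted CTA number to a clinical target (default 400).
    Includes a seeded synthetic patient-cohort generator with truncated
    normal marginals, agreement statistics for verification cohorts,
    lossless JSON model serialization, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
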