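Package: syncoscore
Title: Prehospital Syncope Risk Scoring with NEWS2 and Point-of-Care Lactate
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for prehospital risk stratification of syncope patients.
    Implements the National Early Warning Score 2 (NEWS2) vital-sign rubric
    with per-parameter sub-scores and escalation flags, the NEWS2-L composite
    (NEWS2 total plus point-of-care lactate in mmol/L), a full
    diagnostic-accuracy panel (sensitivity, specificity, predictive values,
    likelihood ratios, diagnostic odds ratio and accuracy, with confidence
    intervals), ROC curve construction with DeLong variance and paired AUC
    comparison, Youden-index cut-off selection, and a seeded synthetic cohort
    generator calibrated to published survivor/non-survivor vital-sign and
    outcome distributions so the whole pipeline is testable without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
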