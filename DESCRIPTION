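Package: msofa
Title: Modified Sequential Organ Function Assessment Scoring and Mortality Discrimination
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Computes the six-organ Sequential Organ Function Assessment (SOFA)
    severity score and its pulse-oximetry modification (mSOFA), in which the
    SpO2/FiO2 ratio replaces the PaO2/FiO2 ratio so the respiratory component
    can be scored without blood gas analysis. Provides a cohort pipeline that
    reads long-format ICU observation tables, applies eligibility rules,
    selects worst values per 24-hour window with single-gap imputation, and
    derives the admission, 48-hour, mean, highest, delta and total score
    family per patient; a statistical layer with survivor/non-survivor
    comparisons, empirical AUROC, DeLong confidence intervals and paired AUC
    tests, and multivariable logistic regression odds ratios; and a seeded
    synthetic ICU-cohort generator for end-to-end testing without patient
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
    withr,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
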