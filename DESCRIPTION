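Package: dieteval
Title: Validation of Automated Dietary Assessment Tools Against Weighed Food Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A four-stage framework for validating automated dietary-assessment
    tools (photo- or barcode-based food-record apps) against weighed food
    diaries, the gold standard for dietary intake. Quantifies segmentation
    accuracy (found/omitted/intruded edible components), classification
    accuracy over a hierarchical food taxonomy (exact/close/far/mismatch
    grades, Cohen and Brennan-Prediger uniform kappa, sensitivity and
    specificity with exact Clopper-Pearson intervals), portion-size error for
    exactly classified segments, and energy/macronutrient agreement by
    regression calibration with heteroscedastic 95% limits of agreement and
    coefficient-of-variation summaries. Includes a seeded synthetic-study
    generator emulating the measurement-error structure of such validation
    studies, so every pipeline stage is testable without access to raw records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
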