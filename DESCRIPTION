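Package: sepsieval
Title: Evaluation Strategies for Sepsis Onset Prediction Models in the ICU
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating early-warning models for sepsis onset in
    intensive care. Implements Sepsis-3 onset labeling from antibiotic and
    SOFA event streams, cohort eligibility filtering, hourly preprocessing
    with forward-fill imputation and temporal feature engineering, three
    evaluation strategies (fixed horizon, peak score, continuous) with
    optional case-control onset matching and prevalence harmonization, a
    weighted metric suite (AUROC, AUPRC, lifted variants, Brier score,
    decision curves, alarm rates with silencing), cross-validated isotonic
    calibration, paired bootstrap significance testing with Holm correction,
    and a seeded synthetic ICU cohort generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
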