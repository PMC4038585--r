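Package: momscreen
Title: First-Trimester Serum Screening Statistics with Multiple-of-Median Normalization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for first-trimester case-control screening studies of
    pregnancy complications such as preeclampsia: a synthetic cohort generator
    with gestational-age-dependent analyte medians and below-limit-of-detection
    censoring, detection-rate filtering and half-minimum imputation,
    gestation-specific multiple-of-median (MoM) normalization with
    Cuckle-Wald covariate adjustment, Student's t marker pre-selection with
    Benjamini-Hochberg false-discovery-rate control, logistic prior-risk and
    combined marker risk models, and screening-performance evaluation as the
    detection rate at a fixed false-positive rate with Wilson confidence
    intervals and Mann-Whitney AUC. A single pipeline driver replays the whole
    train/test/validation study design end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stats,
    utils,
    ggplot2,
    generics,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
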