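Package: accelcut
Title: Accelerometer Cut-Point Calibration and Cross-Validation for Older Adults
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for calibrating accelerometer intensity cut-points
    against indirect calorimetry in older adults and cross-validating them on
    an independent activity protocol. Converts raw tri-axial acceleration into
    ENMO (Euclidean Norm Minus One g) and band-pass activity counts on 5 s
    epochs, derives steady-state MET values from breath-by-breath gas
    exchange, builds ROC curves per wear site and acceleration metric with
    DeLong confidence intervals and AUC comparisons, selects thresholds
    minimising the squared distance to perfect sensitivity and specificity,
    and applies fixed thresholds to an independent sample. Includes a
    synthetic-data generator that emulates a laboratory calibration protocol
    with known ground-truth intensity structure.
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
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
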