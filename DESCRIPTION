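Package: hvfcast
Title: Forecasting Humphrey Visual Fields from a Single Test
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for single-field forecasting of Humphrey 24-2 visual
    fields. Provides the 8x9 masked-grid data model for 54-point perimetry
    records, a calibrated synthetic longitudinal glaucoma cohort simulator,
    temporal pair construction with 0.5-year interval binning and
    patient-level cross-validation splits, three pointwise linear
    progression baselines (simulated and empirical rate-of-progression
    models and per-point regression) with the Gaussian theoretical lower
    bound on pointwise mean absolute error, a compact convolutional
    regression engine (cascade, residual, batch-norm and fully connected
    families) trained with a masked pointwise mean absolute error loss and
    an interval transfer-learning chain, and an evaluation suite with
    cluster-bootstrap confidence intervals and Bland-Altman mean-deviation
    agreement. All user-facing functions take and return tidy data frames.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
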