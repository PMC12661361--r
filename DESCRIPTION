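Package: enosedx
Title: Electronic-Nose Signal Classification for Gynaecological Cancer
    Diagnostics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable, tested pipeline for diagnosing ovarian and
    endometrial cancer from plasma volatile-organic-compound (VOC)
    measurements made with a 32-sensor metal-oxide-semiconductor (MOS)
    electronic nose. Covers the full analysis chain: a synthetic cohort
    generator with planted class structure, batch effects and
    non-discriminative sensors; per-signal preprocessing (alignment,
    baseline correction, smoothing, normalization); extraction of 85
    statistical, time-domain and frequency-domain features per signal;
    Pearson-similarity sensor-utility ranking with iterative sensor
    elimination; a from-scratch Gentle AdaBoost classifier built on
    weighted-least-squares regression stumps with grouped 5-fold
    cross-validation and a budgeted seeded hyperparameter search;
    threshold-gated majority voting to aggregate per-signal predictions
    to sample-level decisions; a four-classifier cascade producing a
    five-way diagnosis (healthy, ovarian or endometrial cancer, FIGO
    stage I vs II-IV); and evaluation utilities (confusion metrics with
    Wald confidence intervals, repeated train/test robustness
    assessment, learning curves).
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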