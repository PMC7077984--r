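Package: breathr
Title: Breath-Level Analysis of Opioid-Induced Respiratory Depression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying opioid-induced respiratory depression
    (OIRD) from whole-body plethysmography airflow recordings and from in
    vitro preBotzinger Complex population recordings. Breaths are segmented
    at signed zero-crossings of airflow with configurable quality control;
    per-breath features include inspiratory and expiratory durations, the
    expiratory pause (time below an airflow threshold), peak flows,
    approximated tidal volume and minute ventilation. Per-animal summaries
    feed paired morphine/saline ratio statistics (normality-gated paired
    tests with paired Cohen's d) and mixed repeated-measures ANOVA. Slice
    recordings are band-pass filtered and integrated for burst detection,
    baseline-normalized dose-response curves and rhythm-cessation
    classification. A synthetic-data generator emulates saline and morphine
    breathing regimes and slice rhythms with exact ground truth so every
    stage of the pipeline can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
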