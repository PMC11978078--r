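Package: pricequiv
Title: Equivalence Testing and Concordance for Multi-Source Market Price Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for validating market price series collected through
    different channels (trained enumerators, crowdsourced submissions, and
    model-imputed monthly estimates) against one another. Provides a
    synthetic-data generator built on latent log-price random walks with
    skewed exponential-power (generalized error) innovations and per-source
    observation layers; preprocessing utilities that standardise heterogeneous
    packaging units to price per kilogram, screen outliers with Tukey fences
    and plausibility bounds, and aggregate submissions to daily, weekly or
    monthly means; Pearson concordance with lead-lag profiles and
    nearest-market spatial matching; a formal equivalence suite combining
    Shapiro-Wilk normality of the paired difference sequence, a paired t-test
    against a fixed markup, and a two-sided variance-ratio F-test, with a
    three-level agreement classifier; and a Monte-Carlo study harness that
    verifies calibration, power, markup recovery and the
    aggregation-improves-correlation effect of the whole framework.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    tibble,
    readr,
    lubridate,
    geosphere,
    jsonlite,
    rlang,
    withr,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
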