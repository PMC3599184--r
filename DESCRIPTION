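Package: raiaudit
Title: Data-Quality Auditing for RAI 2.0 / MDS Continuing-Care Assessment Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An audit pipeline for longitudinal interRAI RAI 2.0 (Minimum Data
    Set) assessment records of the kind submitted to continuing-care reporting
    systems. Scores the embedded clinical scales (Cognitive Performance Scale,
    ADL Long Form, RUG-ADL, Depression Rating Scale, Aggressive Behaviour
    Scale, Pain Scale), detects cross-sectional logical coding errors,
    longitudinal diagnosis reversals and probable autopopulation
    (carry-forward) of item blocks, categorizes sign-off lags, and tracks data
    quality over time through quarterly stratified indicator series, ordinary
    least-squares trend fits, Cronbach's alpha reliability series, convergent
    validity statistics (Pearson, Spearman, Cramer's V) and cross-setting
    concordance. Includes a calibrated synthetic two-sector cohort generator
    with labelled error injection so every detector and statistic is testable
    without access to protected health records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    yaml,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
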