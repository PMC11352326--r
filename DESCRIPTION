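Package: targetheight
Title: Corrected Mid-Parental Target Height Prediction and Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts a child's adult target height from parental heights
    with corrections for parental age-related shrinkage, sex (additive,
    multiplicative or Z-score standardization), and regression to the mean,
    and assesses whether the deviation of a child's projected height from
    the target is within the normal range via an empirical within-family
    residual distribution. Includes the offspring-on-midparent regression
    pipeline for comparing correction schemes on nuclear-family cohorts,
    growth-chart percentile utilities, and a synthetic family-cohort
    simulator with the same statistical structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
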