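Package: phenosense
Title: Smartphone Digital Phenotyping for Adolescent Mental-Health Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for predicting mental-health risk from
    smartphone digital-phenotyping data. Generates synthetic longitudinal
    cohorts (daily 1-7 self-reports plus eight passive sensor streams with
    realistic opt-in gating and engagement decay), engineers the 92-feature
    passive set (GPS mobility, app usage, ambient light, background noise,
    battery, screen brightness, steps, in-app usage) with day/night windows
    and sentinel coding, stabilises daily features by cumulative-median
    aggregation, pretrains a user-day encoder with triplet-margin
    contrastive learning, fine-tunes frozen-encoder binary risk classifiers
    with inverse-frequency class weighting, and evaluates them with
    leave-one-subject-out cross-validation, paired significance tests,
    external-validation and subgroup reports, Spearman association screens
    with Benjamini-Hochberg control, and sampling-Shapley attributions
    aggregated by sensor.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    geosphere,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
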