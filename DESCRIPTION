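Package: lexigaze
Title: Stimulus Design and Gaze Analysis for Infant Audiovisual
    Statistical-Learning Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and analysing infant preferential-looking
    experiments in which trisyllabic nonsense words are learned from a
    continuous audiovisual stream. Constructs harmony-cued word inventories and
    transitional-probability-balanced familiarization streams, counterbalanced
    two-alternative test-trial schedules, and validates their combinatorial
    invariants. Provides a synthetic infant-gaze simulator (50 Hz remote
    eye-tracker emulation with configurable ground-truth preference), a
    dispersion-threshold (I-DT) fixation parser with area-of-interest
    assignment, valid-trial quality control, the data-driven identification of
    the lateralization analysis window, and the looking-time learning metrics
    (first gaze, total looking time and longest-fixation proportions and
    accuracies) with their group-level inference (one-sample and paired t
    tests with Cohen's d, two-way between-subjects ANOVA with partial eta
    squared, ANCOVA, correlations, chi-square, Holm correction).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
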