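Package: sociodyn
Title: Social Behavior Dynamics, Neural Response Classification, and
    Intrinsic Electrophysiology Feature Extraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for studies of social behavior and its neural
    correlates. Implements first-order Markov transition analysis of annotated
    behavior sequences (G-statistic order test and likelihood-ratio
    stationarity test, in full-alphabet and two-state social/nonsocial forms),
    pose-geometry detection of cup interactions in the three-chamber assay
    with trial extraction rules, threshold-sweep auROC classification of
    calcium-imaged neurons against a circular-shift permutation null,
    event-triggered averaging and Ward-linkage clustering of response
    profiles, current-clamp intrinsic-property extraction (voltage sag, ramp
    ratio, rheobase firing delay, maximal instantaneous frequency) with
    optogenetic PSP metrics and response classification, and scalar behavior
    metrics (tube-test relative dominance, social:object preference ratio).
    A synthetic-data module generates every input class with planted ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
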