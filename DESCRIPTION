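Package: negconn
Title: Negative Connectivity Between Default-Mode and Task-Positive
    Networks in Longitudinal Resting-State fMRI Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for studying anticorrelation between the
    default-mode network and task-positive networks in parcellated
    resting-state BOLD data. Covers framewise-displacement motion
    censoring with fixed-duration clean-frame selection, per-scan
    Fisher-z connectivity matrices, reference-defined anticorrelated
    edge masks (threshold and density rules), an averaged
    negative-connectivity metric, longitudinal linear mixed-effects
    inference with AIC model selection, edgewise fits with
    Benjamini-Hochberg correction and summed-t region scores,
    gender-balanced permutation resampling, signal-detection d-prime
    scoring of identical-pairs continuous performance task logs, and
    brain-behavior coupling models. Includes a synthetic longitudinal
    cohort generator with closed-form oracles so every stage can be
    validated end-to-end without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
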