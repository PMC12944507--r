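Package: osascreen
Title: Awake Obstructive Sleep Apnea Screening from Tracheal Breathing Sounds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Two-level ensemble framework for screening obstructive sleep
    apnea (OSA) during wakefulness from noisy tracheal breathing sound
    recordings. Implements breath-phase segmentation by log-variance
    envelope, signal-to-noise gating, wavelet packet (sym8, 5 levels)
    acoustic feature extraction, balanced-subset mRMR stability feature
    selection, nine anthropometric sub-classifiers of balanced bagged
    decision trees fused by dynamic probability voting, and the full
    cross-validated evaluation harness (threshold sweep, leave-one-
    subgroup-out fusion, non-stratified baseline, intermediate-AHI group).
    Includes a seeded synthetic cohort generator (metadata plus audio)
    emulating the recording protocol so the whole pipeline is testable
    without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    rpart,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
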