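Package: infantdyn
Title: Dynamic Analysis of Infant Movement and Self-Regulatory Behaviour
Version: 0.1.0
Authors@R: person("TEBC", "Analytics", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Two-level dynamic analysis of infant movement during the
    still-face paradigm. Study-1-style motor analysis: low-pass filtering of
    wearable tri-axial free acceleration, acceleration magnitude, phase
    segmentation, improved multiscale permutation entropy over 50 scale
    factors, and complexity indices mapped onto EEG-style frequency bands
    (gamma, beta, alpha, theta, delta). Study-2-style behavioural analysis:
    chromatic auto-recurrence quantification (recurrence rate, laminarity,
    trapping time, block entropy) of 1 Hz categorical emotional
    self-regulation sequences. Includes a synthetic-data generator emulating
    the phase-by-group cohort design so the full pipeline is testable
    without restricted cohort data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
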