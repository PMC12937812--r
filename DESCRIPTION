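Package: nfsim
Title: Simulated Real-Time fMRI Neurofeedback: Decoding, Feedback Replay and
    Group Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: End-to-end simulation and analysis of closed-loop real-time fMRI
    neurofeedback experiments built around motor imagery and paced finger
    tapping. Generates seeded synthetic BOLD sessions (block schedules,
    planted motor-network activation convolved with a canonical HRF, drift,
    motion-coupled nuisance and Gaussian noise) together with tapping
    behavior; trains a linear support vector machine to separate tapping from
    rest under visual-cortex exclusion masking; replays imagery runs through
    a latency-aware feedback state machine with incremental online nuisance
    regression; scores tapping behavior (instantaneous rate RMSE, missed-tap
    fraction, pre/post improvement); and performs first-level GLMs, group
    one-sample and covariate t maps with cluster-extent thresholding, plus
    the accompanying behavioral statistics (one-sample t from raw or summary
    data, repeated-measures ANOVA with Mauchly/Greenhouse-Geisser handling,
    Wilcoxon signed-rank, Spearman correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    RNifti,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
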