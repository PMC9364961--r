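Package: sleepstager
Title: Automatic Sleep Staging with a Parallel CNN-LSTM and Hilbert-Huang EEG Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Five-stage (W, N1, N2, N3, REM) automatic sleep staging from
    30-second EEG/EOG epochs using a parallel convolutional and LSTM
    feature-fusion network, trained with an imbalance-aware per-night
    resampling regimen and a step-decayed stochastic gradient descent
    schedule.  Includes a synthetic polysomnography generator that renders
    the canonical per-stage EEG rhythms (delta, theta, alpha, beta) and
    transient events (spindles, K-complexes, sawtooth waves, blinks, rapid
    eye movements) so the full pipeline is testable without clinical
    recordings, an empirical mode decomposition and Hilbert
    instantaneous-frequency analysis of sleep EEG, a precision/recall/F1
    evaluation suite, and EDF import/export with plain-text hypnogram
    sidecars.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    caret,
    jsonlite
Config/testthat/edition: 3
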