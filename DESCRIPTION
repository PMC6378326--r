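Package: fripple
Title: Event-Locked Analysis of Neocortical Fast Ripples and Slow-Oscillation Coupling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for event-locked analysis of multichannel extracellular
    recordings in which pathologic fast ripples (200-550 Hz) ride on
    interictal discharges nested in a large-scale 3-5 Hz slow oscillation.
    Provides fast-ripple and multiunit detectors, Stockwell and Morlet
    time-frequency transforms with baseline z-scoring, circular statistics
    for phase locking and inter-regional phase synchrony, Kullback-Leibler
    modulation-index phase-amplitude coupling, band-limited cross-correlation
    lags, Kalman-filtered time-varying autoregressive modelling with
    (integrated) adaptive partial directed coherence, peri-event spike-train
    analyses, and a seeded synthetic-recording generator with ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    tools,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
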