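Package: deemd
Title: Denoised Ensemble Empirical Mode Decomposition and Spatial
    Pyramid Pooling Classification for EEG-Like Biosignals
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for decomposing neurophysiological time series by
    empirical mode decomposition (EMD) and its noise-assisted ensemble
    variant (EEMD), selecting signal-dominant intrinsic mode functions
    (IMFs) against Monte-Carlo white-noise references (skewness/kurtosis
    shape tests for the first IMF, energy-density versus averaged-period
    spread-line tests for deeper IMFs), extracting a 21-dimensional
    time/frequency feature descriptor per IMF (Hjorth parameters, Higuchi
    fractal dimension, Hilbert-envelope statistics, instantaneous-frequency
    variability, Welch spectral moments), and classifying variable-size
    per-trial feature maps with a small convolutional network topped by a
    spatial pyramid pooling layer. Includes a reproducible synthetic EEG
    trial generator and a command-line pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
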