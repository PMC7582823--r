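Package: hybridbci
Title: Hybrid SSVEP and Eye-Blink Brain-Computer Interface Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, decoding and closed-loop evaluation of a hybrid
    brain-computer interface that combines steady-state visually evoked
    potentials (SSVEP) with voluntary eye blinks on a single bipolar
    occipital EEG channel. Provides a synthetic EEG generator (harmonic
    SSVEP responses and blink transients in 1/f background noise), zero-phase
    IIR band-pass preprocessing, short-time Fourier transform spectrogram
    features, a compact four-layer convolutional neural network trained by
    mini-batch gradient descent on a mean-squared-error loss, a hierarchical
    6x6 menu state machine with blink confirm/undo, and Wolpaw information
    transfer rate and session timing metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    data.table,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
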