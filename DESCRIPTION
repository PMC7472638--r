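Package: eegcontrast
Title: Contrast-Driven Valence Shifts Measured by EEG-Based Emotion Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for studying how linear contrast manipulation of
    visual scenes shifts emotion decoded from EEG. Provides an HSV-space
    linear contrast operator with contrast/intensity change metrics, a
    synthetic generator of DEAP-shaped EEG sessions with label-linked
    spectral structure (frontal alpha asymmetry for valence, beta power for
    arousal) over a 1/f background, DEAP-style preprocessing (downsampling
    to 128 Hz, 4-45 Hz band-pass, peripheral-channel exclusion, baseline
    trimming), construction of 32x32 channel-by-time model inputs with a
    participant-level 22/5/5 split, a multi-column convolutional
    valence/arousal recognizer trained by Adam on a mean-squared-error
    regression loss, and Welch t-test condition comparisons with ordering
    and ranking analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
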