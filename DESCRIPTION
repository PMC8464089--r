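Package: eegrhythms
Title: Nonlinear Features of EEG Rhythms for Epileptic Seizure Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Decomposes single-channel EEG segments into the classical
    delta, theta, alpha and beta rhythms with fourth-order Butterworth
    band-pass filters, computes six nonlinear measures per signal (Higuchi
    and Katz fractal dimensions, rescaled-range Hurst exponent, and
    Lempel-Ziv complexity under mean and median thresholds) for a
    30-dimensional feature vector, ranks features with multi-class
    ReliefF, and evaluates classifiers (tanh multi-layer perceptron,
    linear and radial-basis SVM) by sequential feature addition under
    nested stratified ten-fold cross-validation.  Ships generators for
    fractional Gaussian noise (exact circulant embedding), Weierstrass
    cosine signals of known fractal dimension, and a five-class synthetic
    corpus mimicking the structure of the Bonn EEG benchmark, plus a
    reader and writer for the Bonn plain-text segment format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    graphics,
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
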