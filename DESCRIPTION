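Package: korosound
Title: Korotkoff-Sound Signal Processing, Feature Extraction and
    Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing Korotkoff sounds (KS), the pulse-synchronous
    sounds recorded over the brachial artery during cuff-deflation blood
    pressure measurement. Provides Wiener-filter denoising, Shannon-energy
    envelope segmentation with anchor-point localisation and artifact
    rejection, a 46-dimensional feature extractor (wavelet-packet band
    energies, per-beat energy-ratio variability, time-domain statistics,
    signal and spectral entropy, and Mel-frequency cepstral coefficients),
    a Bayesian-optimised support vector machine plus eleven baseline
    classifier presets for healthy versus chronic-heart-failure screening,
    before/after Valsalva-maneuver variation analysis, and a synthetic KS
    record generator with ground-truth beat times for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    rpart,
    randomForest,
    lhs,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
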