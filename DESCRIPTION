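Package: eegfatigue
Title: Three-Degree Mental Fatigue Recognition from Multichannel EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end pipeline for recognizing three degrees of mental
    fatigue from 19-channel EEG recordings. Implements denoising by
    complementary ensemble empirical mode decomposition (CEEMD) combined
    with independent component analysis, where sample entropy selects the
    noise-carrying intrinsic mode functions and the noisiest independent
    component is removed before reconstruction. Extracts relative band
    power (delta, theta, alpha, beta) from Welch spectra and fuzzy entropy
    per channel, and trains subject-specific gradient-boosted tree
    classifiers evaluated with accuracy and macro-averaged precision,
    recall and F1. Includes a synthetic multichannel EEG generator with
    state-dependent band-power and complexity profiles so the full
    pipeline can be exercised and validated without access to clinical
    recordings, plus baseline preprocessing methods (low-pass filtering,
    db4 wavelet soft thresholding, CEEMD with discarded leading modes)
    and comparison classifiers (SVM, random forest, AdaBoost).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    xgboost,
    e1071,
    randomForest,
    rpart,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
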