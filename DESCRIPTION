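Package: museeg
Title: Decoding Music-Evoked Emotions from EEG Feature Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis pipeline for distinguishing four
    music-evoked emotions (calm, joy, sad, angry) from multi-channel EEG.
    Implements per-electrode extraction of 18 linear band features (peak,
    mean, variance, centre frequency, maximum power, power sum over theta,
    alpha and beta) and 9 nonlinear dynamics features (singular spectral
    entropy, correlation (K2) entropy, approximate entropy, largest Lyapunov
    exponent, C0 complexity, sample entropy, spectral entropy, Lempel-Ziv
    complexity, correlation dimension); correlation-based feature selection
    with symmetric uncertainty and greedy merit search; repeated
    cross-validated benchmarking of SVM, decision-tree, neural-network and
    LDA classifiers; and the accompanying statistical reports (paired t-test
    non-rejection counts, Levene and one-way ANOVA utilities, selection
    frequency histograms). A synthetic EEG generator with controllable,
    emotion-dependent band-power and complexity structure makes every stage
    testable without access to recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    signal,
    e1071,
    rpart,
    nnet,
    MASS,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    car
Config/testthat/edition: 3
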