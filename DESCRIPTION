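Package: eegworkload
Title: EEG Cognitive-Workload Decoding for Pronoun-Resolution Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for binary cognitive-workload
    decoding from 14-channel, 128 Hz EEG recorded during a pronoun-resolution
    task with ambiguous (Class 0) and unambiguous (Class 1) trials. Provides a
    synthetic session generator with controllable band-power effects, FIR
    bandpass preprocessing and trial segmentation, DFT band-power features
    (theta, alpha, mean of beta and gamma per channel), scalp topographic-map
    rendering, from-scratch LeNet-5 / GoogLeNet / EfficientNet-B0 feature
    extractors, PCA early feature fusion, shallow classifiers (naive Bayes,
    C-SVM, k-nearest-neighbour, softmax head), confusion-matrix evaluation
    protocols (hold-out, k-fold, per-subject repetition), and behavioural
    statistics (reaction-time and band-power two-sample t-tests, baseline
    habituation analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    signal,
    e1071,
    nnet,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
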