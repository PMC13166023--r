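Package: ssrime
Title: Scale-Stabilized Relative Intrinsic Mode Energy Features for EEG
    Workload Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Feature extraction and evaluation for EEG cognitive-workload
    decoding based on scale-stabilized relative intrinsic mode energy
    (SS-RIME).  Signals are decomposed with CEEMDAN (complete ensemble
    empirical mode decomposition with adaptive noise), each intrinsic mode
    function is analysed through its Hilbert analytic signal, and per-mode
    energies are stabilized by an instantaneous-frequency dispersion
    penalty, weighted by delta/theta spectral content, and normalized
    across modes.  Includes relative-IMF-energy, relative-wavelet-energy
    and PSD band-power baselines, a seeded synthetic generator of
    workload-labelled multichannel EEG epochs, Fisher-score and
    cross-validated classification harnesses with ablation support, plain
    text and EDF input, preprocessing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    class,
    e1071,
    jsonlite,
    nnet,
    randomForest,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
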