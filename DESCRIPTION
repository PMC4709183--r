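Package: plvspeller
Title: Phase-Synchrony Features and Decoding for P300 Spellers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing P300 speller brain-computer interface
    experiments with inter-channel phase synchrony. Models the row/column
    oddball stimulus paradigm, simulates multichannel EEG sessions with
    known evoked responses and phase coupling, preprocesses continuous
    recordings (zero-phase FIR band-pass, ICA-based blink rejection,
    epoching, baseline z-scoring), extracts classical ERP features (peak
    picking, area, complex Morlet time-frequency maps), computes
    Hilbert-phase phase-locking values (PLV) across trials with
    phase-randomised surrogate significance testing and edge counting, and
    decodes attended characters with a linear SVM, including
    accuracy/AUC-versus-trial-count evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    graphics,
    jsonlite,
    pROC,
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
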