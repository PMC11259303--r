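Package: vimseeg
Title: Wavelet-Packet EEG Features and GRU Models for VR Motion-Sickness
    Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and predicts visually induced motion sickness (VIMS)
    from multi-channel EEG. Implements the full analysis chain: EEG
    preprocessing (band-pass filtering, channel selection, bilateral-mastoid
    re-referencing, PCA artifact removal, fixed-width epoching), wavelet
    packet decomposition with db4 and frequency-ordered band reconstruction
    of the delta/theta/alpha/beta rhythms, 16-item Simulator Sickness
    Questionnaire (SSQ) scoring, a gated recurrent unit (GRU) classifier of
    normal versus motion-sickness windows, a GRU regressor mapping
    baseline-deviation features to SSQ-scaled sickness level, sliding-window
    real-time prediction, and evaluation (confusion matrix, accuracy,
    specificity, sensitivity, PLCC, SROCC, RMSE). Ships a synthetic EEG and
    SSQ corpus generator so the pipeline is testable end-to-end without
    access to recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
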