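Package: stepop
Title: Short-Term Prediction of Intraoperative Hypotension from Arterial Waveforms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for five-minute-ahead prediction of
    intraoperative hypotension from 20-second arterial blood pressure
    waveform segments: artifact screening against physiologic-range
    criteria, moving-average event labeling, cardiac-cycle slicing and
    beat normalization, hemodynamic feature extraction, a 1-D
    convolutional network on the scaled waveform, a stacked bidirectional
    LSTM on the beat matrix, a regularized logistic baseline on 12
    waveform features, and a weighted-average ensemble whose mixing
    weight is tuned by maximizing the area under the precision-recall
    curve. Includes a synthetic arterial-waveform simulator with known
    event schedules and artifact injection so the whole pipeline is
    testable without patient data, and precision-recall evaluation with
    subsampling bootstrap confidence intervals.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    glmnet,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
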