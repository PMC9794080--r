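Package: ecgflow
Title: End-to-End ECG Anomaly Detection and Classification with Wavelet
    Time Scattering and LSTM Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for one-dimensional electrocardiogram
    (ECG) analysis: wavelet detrending and denoising, Pan-Tompkins style
    R-peak detection with interval and heart-rate-variability features and
    rule-based screening alerts, a from-scratch 1-D wavelet time scattering
    transform, an LSTM autoencoder anomaly detector with reconstruction
    error thresholding, and multi-class (ARR/CHF/NSR) classification with
    minimum-redundancy-maximum-relevance feature ranking, classical
    learners, and an LSTM sequence classifier. Includes a synthetic ECG
    generator with per-class rhythm presets so every stage is exercisable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    e1071,
    jsonlite,
    MASS,
    randomForest,
    Rcpp,
    rpart,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
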