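Package: memburst
Title: Decoding Verbal Memory State and Performance from Intracranial EEG
    Burst Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects transient high-gamma (80-200 Hz) and beta (15-40 Hz)
    oscillatory bursts in intracranial EEG via topographical analysis of the
    Morlet wavelet transform, renders them as power-scaled Gaussian-kernel
    time series, and trains small one-dimensional convolutional neural
    networks on the stacked burst tensors to classify verbal memory state
    (encoding versus free recall) and performance (recalled versus forgotten
    words; good versus poor recall sessions). Includes a synthetic
    delayed-free-recall session generator with ground-truth burst records, a
    burst signal-to-noise estimator with a normal-identity GLM linking
    experiment covariates to decoder performance, ROC/Youden evaluation
    utilities, and a time-series adaptation of LIME for explaining the
    trained decoders.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
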