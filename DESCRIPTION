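Package: ndoa
Title: Real-Time EEG Depth-of-Anaesthesia Index from Hybrid Statistical Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Computes a real-time depth-of-anaesthesia (DoA) index from
    single-channel EEG sampled at 128 Hz. Raw EEG windows are denoised with a
    wavelet-shrinkage scheme whose threshold adapts to the relative
    permutation-entropy energy of the window, five statistical features
    (sample entropy, fuzzy entropy, permutation entropy, Hurst range
    response, and an eigenvector-pseudospectrum summary of the wavelet
    sub-bands) are extracted from a 10-second sliding window, and a squared
    exponential Gaussian process regression model maps the features to a
    0-100 index updated every second. Includes a synthetic EEG generator for
    end-to-end validation, Bland-Altman and correlation agreement analysis
    against a reference index, and streaming (per-second) execution with the
    four-second start-up delay used by bedside monitors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    Rcpp,
    readr,
    rlang,
    rpart,
    e1071,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    kernlab,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
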