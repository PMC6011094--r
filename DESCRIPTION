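Package: ecgsqi
Title: Signal-Quality Assessment of Single-Lead ECG by Heuristic and Fuzzy Fusion of Quality Indices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Grades the quality of single-lead electrocardiogram segments as
    Excellent, Barely acceptable or Unacceptable. Computes six signal quality
    indices (R-peak detector agreement, QRS band-power ratio, RR-interval
    coefficient of variation, skewness, kurtosis and baseline relative power),
    grades each against published criteria, and fuses the grades either by a
    simple heuristic rule table or by fuzzy comprehensive evaluation with
    Cauchy, trapezoidal and rectangular membership functions, bounded-operator
    synthesis and a weighted-membership decision score. Ships two independent
    R-peak detectors (Hilbert-envelope with dynamic adaptive threshold, and
    stationary-wavelet modulus maxima), a reader for PhysioNet WFDB and plain
    CSV records, a synthetic ECG generator with controllable baseline-wander,
    powerline, EMG and Gaussian noise, and a repeated stratified
    cross-validation harness with ROC and weight-sweep utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    signal,
    jsonlite,
    caret,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
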