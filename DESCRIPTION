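Package: tremorbci
Title: Multimodal Movement-Intention Detection for Tremor Patients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Signal-processing toolkit for detecting the intention of voluntary
    movement in patients with upper-limb tremor, by fusing EEG, surface-EMG and
    inertial (gyroscope/accelerometer/magnetometer) recordings.  Implements a
    Goertzel-based short-time Fourier spectrogram engine with one-sided PSD
    normalization, beta/alpha band-power ratiograms and their event-related
    desynchronization (ERD) quality parameter, time-resolved corticomuscular
    magnitude-squared coherence, a gyroscope-based early-detection algorithm
    for rest tremor, probability-tree fusion of per-channel detectors, and a
    Monte-Carlo artificial-EEG simulator relating the ERD detection threshold
    to the quality parameter.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
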