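Package: radarfall
Title: Fall-Direction Detection from Simulated FMCW Radar Range-Time and
    Doppler-Time Maps
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates frequency-modulated continuous-wave (FMCW) radar
    baseband echoes of a person walking and then falling, derives
    range-time and Doppler-time power maps from the fast-time/slow-time
    data cube, denoises them with a pattern-feature-extraction stage
    (adaptive power thresholding followed by Hampel outlier filtering),
    and classifies the fall direction (forward, backward, left, right,
    or fall from standstill) with a dual-branch convolutional neural
    network trained on the paired maps. Includes a seeded synthetic-data
    generator, evaluation reports (confusion matrix, accuracy, per-class
    recall and precision), and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
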