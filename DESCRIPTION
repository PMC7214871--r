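Package: streamsnn
Title: Streaming-Rollout Training and ANN-to-SNN Conversion for Event Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying event-camera data streams with spiking
    neural networks obtained by conversion from artificial neural networks.
    Implements layered network graphs with temporal skip connections and
    their streaming rollouts (every edge carries a delay of one rollout
    frame), backpropagation-through-time training of the weight-shared
    rollout with a weighted multi-output cross-entropy loss, conversion to
    integrate-and-fire spiking networks via per-layer activation-percentile
    rescaling with matched axonal delays, a time-stepped simulator with a
    windowed spike readout, and operation-count based efficiency evaluation
    (accuracy ratio versus simulation steps per frame). Includes event-stream
    input/output, frame binning, bilinear downscaling and frame stacking, and
    synthetic data generators (moving-rectangles sequences, random event
    streams, random network fixtures).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
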