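Package: spikelin
Title: Parallel Convolutional Spiking Neural Networks with Adaptive
    Lateral Inhibition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pattern recognition with spiking neural networks on
    static images and neuromorphic event streams. Implements an adaptive
    lateral-inhibition image enhancement front-end (Butterworth noise
    pre-suppression and inhibition coefficients that decay exponentially
    with two-dimensional pair entropy), leaky integrate-and-fire neurons
    with closed-form interspike-interval and firing-rate expressions, an
    error-driven membrane time-constant evolution rule, rate and event
    spike encoders, a parallel multi-scale convolutional spiking network
    trained with a windowed STDP-based supervised rule, Wilson-score
    confidence intervals for classification accuracy, seeded synthetic
    image and event-stream generators, and readers and writers for
    IDX, PGM/PNG and 5-byte address-event binary formats.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    generics,
    jsonlite,
    png,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
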