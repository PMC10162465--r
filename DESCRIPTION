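Package: koopstream
Title: Koopman Spectral Feature Extraction for Bistable Auditory Streaming
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts slow, percept-tracking features from minutes-long
    multichannel neural recordings collected during auditory triplet
    streaming. The pipeline standardizes and decimates local field
    potentials, builds exponentially weighted time-delay coordinates,
    computes a diffusion-map basis from a k-nearest-neighbour Gaussian
    kernel Markov matrix, and approximates Koopman eigenvalues, modes and
    eigenfunctions with the extended dynamic mode decomposition. Spectral
    features are organized into a stimulus-encoding and a
    perception-encoding branch, a slowly drifting real eigenfunction that
    tracks the perceptual state is located, and perceptual switches are
    predicted from windowed instantaneous phase. Includes a synthetic
    generator of bistable-streaming recordings and behaviour, constrained
    permutation tests, divergence and reconstruction statistics, and
    plotting helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    RSpectra,
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
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
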