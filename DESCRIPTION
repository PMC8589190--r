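Package: rfpursuit
Title: Receptive-Field Characterization with Pursuit Regression and Fixed-Kernel Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing visual-cortex receptive fields from
    stimulus-response data. Implements projection pursuit regression and its
    convolutional and dictionary-matching variants with quadratic link
    functions, single-layer convolutional response-prediction networks with
    learned or frozen (Gabor, Laplacian-of-Gaussian, or convolutional
    sparse-code) front-ends, convolutional sparse coding for learning
    complex-shaped kernel dictionaries from images, a linear-nonlinear
    synthetic-neuron simulator with signal-dependent noise, binary pattern
    stimulus generation, and scoring utilities (prediction correlation,
    kernel importance, complexity scores, data-efficiency and convergence
    protocols) for discriminating orientation-tuned from higher-order
    neurons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
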