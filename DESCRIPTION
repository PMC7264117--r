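Package: gainfields
Title: Neural Network Models of Eye-Position Gain Fields in Visual Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Rate-based neural network models of eye-position gain modulation
    of retinotopic visual responses. Provides a hardwired population of visual
    neurons whose internal activation is the sum of Gaussian retinal-location
    and eye-position tuning components passed through a sigmoid transfer
    function, and a two-layer self-organizing network in which gain-modulated
    responses emerge through Hebbian learning with competitive (percentile)
    output dynamics and post-update synaptic weight renormalization. Includes
    a generator of randomized fixation/saccade training schedules, analyses of
    tuning-curve linearity (coefficient of determination of a linear fit),
    population histograms across eye-position tuning widths, tests of
    multiplicative gain modulation, response-profile classification, and a
    command-line interface for reproducible experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
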