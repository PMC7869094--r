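Package: sfgdcm
Title: Effective Connectivity Analysis of Auditory Figure-Ground and
    Speech-in-Noise Difficulty
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for linking difficulty in auditory figure-ground and
    speech-in-noise tasks to cortical effective connectivity.  Generates
    stochastic figure-ground tone-cloud stimuli, simulates weighted up-down
    adaptive threshold procedures and signal-detection summaries, forward
    models sparse-sampled BOLD responses of an eight-region auditory network
    with a bilinear neural model coupled to a balloon hemodynamic model,
    inverts the model per subject by variational Laplace, and performs
    hierarchical group inference with parametric empirical Bayes, Bayesian
    model reduction, and Bayesian model averaging with
    posterior-probability thresholding.  A synthetic-experiment module
    generates complete multi-subject datasets (designs, thresholds,
    behaviour, region timeseries) so the whole chain runs without any
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
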