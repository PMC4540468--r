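Package: sheetsampler
Title: Neural Sampling and Self-Organized Learning in Spiking Sheets with
    Local Lateral Inhibition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Discrete-time simulator of sheets of stochastic spiking neurons
    whose state trajectory samples the posterior of an explicit generative
    model (a Boltzmann-machine prior with winner-take-all lateral inhibition
    and exponential-family likelihoods over afferent fields). Provides the
    exact-inference machinery for small networks (state enumeration, closed
    form posteriors, prior-bias calibration, log-likelihood estimation),
    the translation between abstract model parameters and neuronal
    parameters, and the self-organized plasticity rules (Hebbian afferent
    learning, homeostatic intrinsic plasticity, wake-sleep and heuristic
    recurrent learning), together with configured experiment protocols and
    synthetic spiking-input generators.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
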