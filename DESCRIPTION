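Package: memstdp
Title: Compound Memristive Synapses and STDP Learning in Spiking
    Winner-Take-All Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of compound memristive synapses, in which
    a synaptic weight is formed by M bistable stochastic switches operating in
    parallel. Provides the stochastic switching plasticity rule (stochastic
    spike-timing dependent plasticity with a stabilizing weight dependence),
    device-noise models for spatial and temporal conductance variability and
    unbalanced switching probabilities, a stochastic winner-take-all spiking
    network with softmax lateral inhibition and homeostatic intrinsic
    plasticity, the corresponding Mixture-of-Gaussians generative model with
    exact Bayesian posterior and log-likelihood estimation, Poisson encoding
    of intensity patterns into binary pulse traces, synthetic pattern
    generators, and experiment protocols for pairing experiments, unsupervised
    training, neuron labeling and classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
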