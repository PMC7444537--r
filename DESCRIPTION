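Package: ctrnet
Title: Communication Through Resonance in Modular Spiking Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of synchronous spike-volley ("pulse
    packet") propagation through layered networks of excitatory-inhibitory
    spiking modules. Implements a clock-driven, conductance-based
    leaky integrate-and-fire simulator with alpha-function synapses and
    delayed spike delivery (compiled core), stochastic construction of
    feedforward networks (FFN) and resonance-pair networks (RPN) in which
    the first two layers are bidirectionally coupled, Poisson background
    and Gaussian pulse-packet stimulus generators, and the spike-train
    statistics used to quantify propagation: signal-to-noise ratio,
    population Fano factor, spectral entropy, network frequency, pairwise
    correlations and inter-spike-interval variability. Experiment drivers
    reproduce delay/strength sweeps, propagation-threshold and speed
    comparisons, and robustness analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
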