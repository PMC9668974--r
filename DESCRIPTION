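Package: plastlock
Title: Frequency Locking and Spike-Timing-Dependent Plasticity in
    Pulse-Coupled Class I Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Event-driven simulation of networks of pulse-coupled class I
    neurons (quadratic integrate-and-fire and tabulated phase-response-curve
    oscillators) with the additive nearest-neighbor pair-based
    spike-timing-dependent plasticity rule, together with the closed-form
    theory of frequency locking for two coupled neurons: Arnold-tongue
    boundaries with fixed synaptic weights and under plasticity, exact for
    quadratic integrate-and-fire neurons and near resonance for arbitrary
    class I phase response curves.  Includes Wang-Buzsaki and Morris-Lecar
    conductance-based models with adaptive integration, saddle-node-on-
    invariant-circle current localization, numerical phase-response-curve
    extraction and parabolic peak fits, and connectivity-pattern analysis of
    plastic networks (synchronized clusters, emergent slow pacemakers).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
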