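Package: apnet
Title: Assembly Projections in Spiking Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation of disinhibition-gated assembly projections in networks of
    stochastically spiking point neurons. Provides a time-stepped simulation engine
    (exponential-hazard neurons, pair-based STDP with a constant offset, short-term
    synaptic depression), construction of content and structural ("neural") spaces
    with tabulated wiring statistics, rate-coded Poisson input patterns, the
    CREATE / LOAD / RECALL / COPY / COMPARE operation protocols, spike-train
    analysis (low-pass filtering, assembly identification, similarity criterion,
    linear decoders, voxelized fMRI-like signals), and a gradient-free
    plasticity-parameter calibration and robustness harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    glmnet,
    lhs,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
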