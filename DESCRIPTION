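Package: spikecircuit
Title: Spiking-Network Simulation and Microelectrode-Array Spike-Train Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how synaptic-scale perturbations reshape the
    activity and functional organization of cultured neural circuits. Provides
    a conductance-based leaky integrate-and-fire network simulator (AMPA, NMDA
    and GABA-A synapses, spike-triggered after-hyperpolarization, short-term
    plasticity on all synapses and spike-timing-dependent plasticity on
    excitatory-excitatory connections) with perturbation conditions emulating
    cypin overexpression, an entrainment protocol that measures signal
    fidelity between stimulated input neurons and the remaining excitatory
    population, and the analysis stack applied to both simulated and
    microelectrode-array data: band-pass and notch filtering, adaptive
    threshold spike detection, interspike-interval and Fano-factor statistics,
    burstlet and network-burst detection, cross-correlation functional
    connectivity, and weighted graph measures (global and local efficiency,
    Louvain communities, modularity). A synthetic-data module generates
    voltage traces and spike rasters with known ground truth so the whole
    pipeline is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    igraph,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
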