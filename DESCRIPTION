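Package: burstnet
Title: Spiking-Network Simulation and Spectral Burst Analysis for MEA Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates recurrent networks of excitatory adaptive leaky
    integrate-and-fire neurons with conductance synapses and Poisson external
    drive, and analyses micro-electrode-array (MEA) spike trains with a
    surrogate-normalized Welch power-spectral-density pipeline to extract peak
    network-burst frequencies. Includes extracellular spike detection from raw
    voltage, electrode and well quality-control filters, genotype parameter
    fixtures, parameter-scan and drop-out experiments linking single-neuron
    adaptation currents to network burst dynamics, and a ground-truth-known
    synthetic MEA data generator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
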