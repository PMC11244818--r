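Package: plastnet
Title: Metastable Dynamics and Local Voltage-Based Plasticity in Spiking
    Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates recurrent networks of exponential integrate-and-fire
    neurons whose excitatory synapses follow a fully local, voltage-based
    plasticity rule with a BCM-like adaptive threshold. Provides training and
    perturbation protocols that form overlapping cell assemblies, analysis of
    the resulting metastable cluster dynamics (overlaps, hidden-state
    segmentation, dwell-time statistics, weight-class trajectories and their
    scaling with network size), and a mean-field description of the simplified
    clustered network based on the steady-state Fokker-Planck transfer
    function of the exponential integrate-and-fire neuron, including the
    (mu, sigma) landscape of active-cluster solutions and its accessibility
    bound. All simulations are deterministic given a master seed; results are
    returned as tibbles so they compose with the tidyverse.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
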