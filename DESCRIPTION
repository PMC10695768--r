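Package: msbnet
Title: Multi-Synaptic Bouton Networks: Spiking Simulations and Synapse
    Morphometrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how multi-synaptic boutons (MSBs) -- single
    presynaptic terminals contacting spines of several postsynaptic neurons --
    shape population activity and synapse structure in hippocampal CA1.
    Includes a CA3/2 to CA1 leaky integrate-and-fire network simulator with
    stochastic vesicle release and Tsodyks-Markram short-term plasticity,
    spike-train binning and mean pairwise correlation analysis across
    connectivity conditions, estimation statistics for synapse-morphology
    tables (within-bouton versus neighboring single-synaptic-bouton variance,
    Cliff's delta, permutation tests, BCa bootstrap intervals, Ryan-Holm
    adjusted confidence levels), a dendrite self-proximity analysis on SWC
    morphologies, and synthetic-data generators with known ground truth for
    every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    boot,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
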