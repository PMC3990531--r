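Package: socnet
Title: Self-Organized Critical Adaptive Boolean Networks and Neuronal
    Avalanche Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for a minimal adaptive Boolean
    threshold-network model of neuronal self-organized criticality. Provides
    signed directed networks with stochastic (Glauber) and deterministic
    threshold dynamics, a local correlation-based rewiring rule that drives
    the network's branching parameter towards the critical value of one,
    deterministic avalanche generation with a threshold-fatigue (exhaust)
    mechanism, and avalanche scaling statistics: discrete power-law exponent
    estimation for size and duration distributions, the crackling-noise
    exponent relation, and universal avalanche-shape collapse. Includes
    Galton-Watson branching-process ensembles and brute-force oracles used
    for calibration and testing, plus a small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
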