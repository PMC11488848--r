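Package: preplaynet
Title: Place Fields and Preplay in Randomly Clustered Spiking Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates recurrent networks of conductance-based leaky
    integrate-and-fire neurons whose excitatory cells are organized into
    randomly overlapping clusters, and analyzes the resulting activity with
    standard hippocampal place-cell methods. The package constructs clustered
    network realizations with feed-forward spatial and contextual Poisson
    inputs, simulates linear-track traversals and sleep sessions, computes
    binned and smoothed place fields with their summary statistics (peak rate,
    specificity, spatial information, peak-distribution divergence), detects
    population burst events in simulated sleep, decodes candidate events with
    a memoryless Bayesian decoder, and evaluates preplay significance against
    time-bin shuffle nulls (Kolmogorov-Smirnov ensemble test, threshold-grid
    bootstrap, per-event p-values). Directed small-world metrics, cluster
    activation dynamics, cell-identity shuffle controls and multi-environment
    remapping protocols complete the analysis pipeline.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), igraph, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
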