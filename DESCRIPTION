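Package: fcgraph
Title: Graph-Theoretic Analysis of Longitudinal Functional Brain Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for paired (pre/post-treatment) graph analysis of
    resting-state functional connectivity over a small region-of-interest
    parcellation. Builds Pearson connectivity matrices from ROI BOLD time
    series, binarizes them by proportional density thresholding across a
    density sweep, computes nodal and global graph indexes (degree,
    clustering coefficient, nodal average path length, local and global
    efficiency, betweenness centrality), estimates small-worldness against
    degree-preserving rewired null networks, and compares sessions with
    exact Wilcoxon signed-rank tests. Includes a synthetic paired-cohort
    generator with controllable covariance structure and injectable
    connectivity effects so the full pipeline is testable without raw fMRI
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    xml2,
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
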