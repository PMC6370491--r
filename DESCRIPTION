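Package: dfcbench
Title: Benchmarking Confound Regression Pipelines for Dynamic Functional
    Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Evaluation machinery for de-noising strategies in dynamic
    resting-state functional connectivity. Generates synthetic cohorts of
    motion-contaminated parcel time series with planted time-varying
    community structure, applies a registry of nuisance confound regression
    pipelines (realignment parameters and their Friston expansion,
    tissue-mean and local white-matter signals, global signal regression,
    CompCor-style principal components, despiking), builds sliding-window
    Fisher-z connectivity stacks, and scores each pipeline on edge
    dispersion-motion associations, distance-dependent motion artifact,
    multilayer modularity quality obtained by a generalized Louvain
    heuristic, and node flexibility and promiscuity statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
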