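Package: plvnet
Title: Multiband Phase-Locking Brain Networks from EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction and group comparison of static, dynamic and
    cross-frequency EEG functional networks built on the phase-locking value
    (PLV). Provides band-limited instantaneous-phase extraction via the
    analytic signal, low-order (pairwise PLV) and high-order ("correlation of
    correlations") connectivity matrices within and between the canonical
    delta/theta/alpha/beta bands, weighted graph metrics (clustering
    coefficient, characteristic path length, global and local efficiency),
    sliding-window network dynamics with participation-coefficient K-means
    state classification and state entropy, a multilayer supra-adjacency
    matrix with a cross-band global coordination metric, and edgewise
    two-sample comparisons with false-discovery-rate control. A synthetic-EEG
    module simulates cohorts of coupled Kuramoto phase oscillators with 1/f
    background noise and planted group effects, providing ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
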