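Package: rsntopo
Title: Small-World Topology of Voxel-Wise Resting-State Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Voxel-level graph-topology analysis of resting-state fMRI
    networks: nuisance regression and band-pass filtering of voxel
    time-series, low-frequency spectral summaries (band power
    contribution and fALFF), Pearson correlation graphs thresholded over
    a grid, clustering coefficient and characteristic path length,
    small-world indices (gamma, lambda, sigma) against degree-preserving
    Maslov-Sneppen null ensembles, node equalization, and the
    cognitive-versus-perceptual group comparison with one-sample t tests
    and one- and two-way ANOVA under Bonferroni correction. Ships a
    seeded synthetic BOLD generator that emulates the community
    correlation structure and group-dependent low-frequency power the
    analysis assumes, so the full pipeline runs end-to-end without any
    imaging download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    purrr,
    Rcpp,
    readr,
    rlang,
    RNifti,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
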