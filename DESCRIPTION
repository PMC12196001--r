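Package: dyadsync
Title: Interpersonal Neural Synchrony Analysis for Dyadic fNIRS Hyperscanning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for quantifying interpersonal neural
    synchrony between two people recorded simultaneously with functional
    near-infrared spectroscopy (fNIRS). Covers simulation of dyadic
    two-wavelength optical recordings under a block-design emotive
    co-viewing paradigm, channel quality screening, despiking, zero-phase
    band-pass filtering, modified Beer-Lambert conversion to haemoglobin
    concentration changes, per-channel per-block Dynamic Time Warping with
    the normalized distance index (total alignment cost divided by the
    combined series length), aggregation to prefrontal regions of interest,
    and the dyadic statistics relating synchrony to couples'
    relationship-satisfaction difference (Kruskal-Wallis, multiple linear
    regression, Pearson correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
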