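Package: adaptkuramoto
Title: Metastable Cluster Switching in Non-Reciprocal Adaptive Kuramoto Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for Kuramoto phase oscillators with
    non-reciprocal adaptive couplings, where Hebbian and anti-Hebbian plasticity
    rules act on different time scales and induce metastable anti-phase cluster
    states. Provides an Euler-Maruyama integrator with a compiled inner loop,
    Kuramoto order parameters and collective-state classification, detection of
    cluster-switching events and dwell intervals, snapshot-based escape-time
    prediction of which oscillators switch next, linear stability analysis of the
    two-cluster saddle with its analytic spectrum, and the parameter-sweep
    experiments (adaptation-rate phase diagram, noise, connectivity, and
    coupling-dependent-frequency scans).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
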