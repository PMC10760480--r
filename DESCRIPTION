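Package: flickerfit
Title: Single-Channel Gating Kinetics from Filtered Current Fluctuations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of single ion-channel current recordings
    dominated by fast, filter-limited gating ("flicker"). Provides Monte Carlo
    simulation of Markov gating schemes with voltage-dependent rate constants,
    synthesis of realistically filtered and noisy current traces, half-amplitude
    threshold idealization with dead-time censoring, dwell-time and burst
    statistics (log-binned histograms, truncated-exponential mixture fits,
    critical-time burst segmentation), all-points amplitude histograms and
    extended beta-distribution fitting of sub-bandwidth rate constants by a
    zero-order stochastic optimizer, and macroscopic conductance-voltage
    analysis (Boltzmann fits, activation energies, rate-constant voltage fits,
    and open-probability predictions from a star-topology kinetic scheme).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
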