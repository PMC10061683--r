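Package: fluxhop
Title: State-Aware Forward Flux Sampling for Nonadiabatic Rare Events
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trajectory surface hopping with Langevin dynamics coupled to a
    forward flux sampling rare-event driver whose stable regions and
    interfaces are aware of the electronic state. Provides two analytic
    two-state model landscapes (an avoided crossing and a conical
    intersection), a fewest-switches hopping engine with an energy-based
    decoherence correction, flux estimators with and without reset,
    interface shooting cycles with rate-constant error propagation,
    transition-path extraction and statistics, and Arrhenius and
    Landau-Zener rate fits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    rlang,
    stats,
    utils,
    yaml,
    jsonlite,
    ggplot2,
    generics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    minpack.lm
Config/testthat/edition: 3
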