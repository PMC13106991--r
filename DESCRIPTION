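Package: ruffsurv
Title: Daily Nest Survival of Ruffs on Grazed Coastal Meadows
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, preparation and Bayesian analysis of daily nest
    survival (DSR) for ruff (Calidris pugnax) nests on grazed coastal
    meadows. Provides a synthetic-data generator with competing mortality
    causes (predation, storm-surge flooding, cattle trampling, abandonment)
    and a dummy-egg clutch-protection intervention; spatial covariate
    construction (daily nearest-nest, lek, shoreline, meadow-edge and path
    distances); censoring and encoding of nest histories under three
    mortality scenarios and two dataset variants; a hierarchical Bernoulli
    exposure-day survival model with a year random effect fitted by
    Hamiltonian Monte Carlo; and reporting utilities for fate tables,
    posterior summaries and survival prediction curves.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
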