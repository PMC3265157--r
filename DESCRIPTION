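Package: hybridlv
Title: Hybrid Kinetic and Lotka-Volterra Model of Tumour-Immune Competition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator for a two-population competition model in which a
    kinetic layer evolves the activity distributions of tumour and immune
    cell populations under binary-interaction transition kernels (general
    tabulated, separable, or Dirac-delta), a hiding-learning functional mu
    in [0,1] is computed from the squared L2 distance between the two
    distributions, and a macroscopic Lotka-Volterra system takes mu as a
    time-dependent modulation of the predation term. Provides composite
    Simpson quadrature on a truncated activity domain, fixed-step RK4
    integration for both layers, analytic oracles for the equal-rate
    Dirac-delta reduction, equilibrium and first-integral diagnostics,
    seeded fixture generators, tidy accessors and ggplot2 visualisation,
    and a configuration-driven runner with CSV/JSON output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    readr,
    pracma
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    deSolve
Config/testthat/edition: 3
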