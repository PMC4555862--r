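Package: rstarcomp
Title: Stochastic Resource Competition Along Fitness-Inequality Gradients
Version: 1.0.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates two-species competition for a single limiting
    resource in an open (chemostat-like) system with Monod growth
    kinetics, deterministically or with Poisson demographic
    stochasticity in births and deaths. Builds R*-based
    fitness-inequality parameter spaces, runs replicated sweeps over
    gradients of fitness inequality and initial population size,
    classifies competitive outcomes (dominance by the more or less fit
    competitor, dominance at fitness equality, co-persistence, dual
    extinction), and summarizes outcome frequencies as grids suitable
    for heat maps. Includes a command-line interface, CSV/JSON export,
    and a fully reproducible per-replicate seeding scheme.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
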