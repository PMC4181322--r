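Package: litterGDM
Title: Guild-Based Simulation of Plant Litter Decomposition
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-pool, multi-guild simulator of early-stage plant litter
    decomposition in soil. Carbon in four litter fractions (labile and
    persistent solubles, acid-hydrolysable holocellulose, acid
    non-hydrolysable Klason lignin) is consumed by three microbial guilds
    using reverse Michaelis-Menten kinetics, with decay rate coefficients
    throttled by the lignocellulose index of the remaining litter. Includes
    bounded multi-start calibration of genotype-specific parameters against
    incubation observations, a Monte-Carlo parameter perturbation experiment
    with type-II sum-of-squares variance partitioning, litter-chemistry
    indices and chemistry-to-parameter transfer functions, and a synthetic
    observation generator emulating the 112-day incubation sampling scheme.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    car,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
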