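Package: pcfba
Title: Proteome-Constrained Metabolic Modeling and Resource Allocation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds and solves proteome-constrained genome-scale metabolic
    models: enzyme abundance variables with synthesis/dilution balances,
    turnover-number capacity couplings, translation machinery, an unspecified
    (metabolically inactive) protein, compartment proteome and membrane area
    capacity constraints, and maintenance energetics (GAM/NGAM). Growth rate
    is maximized by feasibility bisection over the growth-rate-parameterized
    linear program; glucose-limited chemostats are emulated through
    transporter saturation factors. Includes knockout and capacity
    perturbations, calibration routines (GAM to exchange fluxes, compartment
    capacity to the critical dilution rate, minimal unspecified-protein
    fraction to the maximal growth rate), mitochondrial redox shuttle cost
    analysis, and a bundled miniature compartmentalized yeast-like network
    generator with synthetic chemostat data for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    xml2,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pracma,
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
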