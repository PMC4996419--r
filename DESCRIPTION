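Package: crossfeedr
Title: Resource-Dependent Dynamics of a Two-Strain Cross-Feeding Mutualism
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic and stochastic analysis of a phenomenological model
    of two amino-acid auxotrophic yeast strains that cross-feed each other.
    Provides the saturating-growth ODE model with logistic crowding and
    dilution-imposed death, full fixed-point and Jacobian eigen-analysis,
    bisection location of the saddle-node and competitive-exclusion
    boundaries, classification of the qualitative interaction regime
    (obligate/facultative mutualism, parasitism, amensalism, competition,
    exclusion, collapse) as a function of amino-acid supplementation, an
    exact Gillespie birth-death simulator, a four-strain invasion extension,
    a synthetic daily-dilution plate-experiment generator with optical
    density and flow-cytometry noise, and the estimation procedures
    (relative fitness, bootstrap equilibrium fraction, experimental regime
    calls) used to analyse such plates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
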