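Package: hyperfront
Title: Hypercycle Dynamics, Mutualistic Range-Expansion Fronts and Colony
    Spatial Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models and metrics for cross-feeding microbial mutualists
    spreading over surfaces. Provides deterministic dynamics of two-member
    hypercycles and three-member communities with a parasite, growth-rate
    inference (Malthusian and hyperbolic) from plate-reader style time
    series, closed-form travelling-wave front speeds for the two-species
    mutualistic reaction-diffusion system together with a residual-based
    verifier of the wave ansatz, an explicit finite-difference solver for
    the reaction-diffusion equations with front tracking, a stochastic
    lattice agent-based simulator of colony range expansions with
    cross-feeding, parasitism and antibiotic cross-protection, and spatial
    descriptors of labelled colony snapshots (sector widths, front-edge
    composition, active fraction, expansion speed and box-counting fractal
    dimension).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
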