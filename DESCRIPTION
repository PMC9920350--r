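Package: salrmix
Title: Pattern Formation in Two-Component Monolayers with Competing
    Interactions
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models of self-assembly in binary mixtures of oppositely
    charged particles with competing short- and long-range interactions
    (SALR-type), as arise for charged inclusions in biological membranes
    and charged nanoparticles in near-critical solvents.  Implements an
    exactly solvable triangular-lattice mixture (explicit phase catalog,
    per-site grand potential, coexistence lines and triple points in the
    chemical-potential plane, brute-force unit-cell enumeration as an
    independent oracle), grand-canonical and canonical Metropolis Monte
    Carlo with simulated annealing, a continuous-space molecular-dynamics
    model with truncated Lennard-Jones plus screened-electrostatic pair
    potentials confined by walls, and order-parameter based pattern
    classification connecting simulated configurations to the predicted
    phases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
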