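Package: nucstack
Title: Stacking Interactions of Druglike Heterocycles with Nucleobases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing and predicting pi-stacking interactions
    between small aromatic heterocycles and the natural RNA/DNA nucleobases.
    Builds parallel stacked dimers and random pose ensembles, computes
    electrostatic-potential (ESP) descriptors on a plane offset from the
    molecular plane restricted to the van der Waals projection, fits a
    two-parameter model of the maximum (global-minimum) stacking interaction
    from heavy-atom counts and ESP descriptors, screens heterocycle libraries
    against the five nucleobases, evaluates fixed-charge molecular-mechanics
    (Coulomb plus 12-6 Lennard-Jones) interaction energies with fitted
    heavy-atom-pair scaling constants, and provides the accompanying analysis
    statistics (SAPT component correlations, per-pair minima summaries,
    nucleobase cross-correlations, tautomer stacking shifts, and stacking
    efficiencies). Includes seeded synthetic-data generators so every
    component is testable without external quantum-chemistry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    bio3d,
    ChemmineR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
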