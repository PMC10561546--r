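Package: squarescheme
Title: Square-Scheme Thermodynamics and Surrogate Models for
    Two-Proton Two-Electron Redox Chemistry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Assembles nine-state square schemes for two-proton
    two-electron redox couples from aqueous Gibbs free energies,
    derives reduction potentials via a computational standard hydrogen
    electrode, acidity constants via an isodesmic reference-acid
    calibration with an empirical linear correction, and Pourbaix
    (pH-potential) predominance diagrams with reduction-pathway
    classification. Includes extended-connectivity fingerprint and
    frontier-orbital descriptors, a seeded random-forest regressor with
    out-of-bag scoring and TreeSHAP feature attributions for training
    surrogate models of those observables, reaction-table input/output
    with SMILES deduplication, and thermodynamically consistent
    synthetic data generators for download-free testing.
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
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
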