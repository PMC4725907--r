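Package: oligodmd
Title: Discrete Molecular Dynamics of Peptide-Polyphenol Oligomers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Event-driven discrete molecular dynamics (DMD) for coarse-grained
    mixtures of the amyloidogenic peptide IAPP (amylin) with small aromatic
    molecules (aspirin, curcumin, resveratrol), together with the aggregation
    statistics used to characterise the resulting assemblies: inter-molecular
    contact maps under a 5.5 Angstrom rule, contact-graph clustering,
    mass-weighted cluster-size distributions and compositions, radial
    core/corona profiles about cluster centres of mass, a backbone
    pseudo-dihedral secondary-structure assignment, and replicate
    orchestration with last-half steady-state averaging. Includes synthetic
    trajectory generators with known ground truth so every analysis stage is
    testable without running production simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    jsonlite,
    igraph,
    generics,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    pracma
Config/testthat/edition: 3
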