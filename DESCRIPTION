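Package: pullpmf
Title: Contact-Map Steered Dissociation Analysis for Protein-DNA Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for quantifying the sequence specificity of protein-DNA
    complexes from steered molecular dynamics. Builds smooth contact-map
    collective variables between protein hydrogen-bond donors and DNA groove
    acceptors, defines a normalized linear steering coordinate, emits
    steering-engine (PLUMED-dialect) input files, and recovers dissociation
    free-energy profiles from ensembles of non-equilibrium work curves via
    the Jarzynski equality: potentials of mean force with error bands, free
    energy ranges and their sequence differences, Boltzmann-weighted 2D
    mechanism surfaces, dissociation-pathway classification, and
    work-deformation correlations. A steered overdamped-Langevin toy
    simulator with analytic free energies provides ground-truth test data,
    so every estimator is verifiable without a molecular dynamics engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
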