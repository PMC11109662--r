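Package: funnelmeta
Title: Funnel Metadynamics, Free-Energy Reconstruction and Ensemble Analytics
    for Ligand-Binding Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale toolkit for funnel metadynamics binding analysis:
    cone-plus-cylinder funnel restraints, collective variables (ligand-protein
    centre-of-mass distance and a logistic native-contact count), a
    well-tempered metadynamics engine on analytic Langevin toy systems, a
    random-accelerated egress rule, free-energy-surface reconstruction with
    basin and saddle detection, funnel-corrected standard-state binding free
    energies and dissociation constants, and conformational-ensemble analytics
    (dynamic cross-correlation maps, contact occupancy, backbone helicity,
    Kabsch superposition, RMSF increments, C-alpha anchor distances). Includes
    seeded synthetic-data generators with machine-readable ground truth for
    every analysis, plus readers and writers for PLUMED-dialect HILLS/COLVAR
    tables and PDB/DCD ensembles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    bio3d,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
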