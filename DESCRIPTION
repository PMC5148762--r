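Package: surfmc
Title: Rigid-Body Monte Carlo Prediction of Protein Orientation on
    Hydrophobic Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts the most likely orientations of a rigid protein
    adsorbed onto a hydrophobic graphene surface by Metropolis Monte Carlo
    sampling of rigid-body poses. The scoring function combines a
    Lennard-Jones protein-surface term with a nonpolar implicit-solvation
    term proportional to the solvent-accessible surface area (SASA) of
    hydrophobic and hydrophilic atom groups. Includes a periodic graphene
    lattice builder, an ideal amphipathic helix fixture generator,
    orientation and per-residue surface-contact analyses, free-energy
    heatmaps over principal-axis angles, and amide-I exciton sum-frequency
    generation (SFG) spectrum calculations for validating predicted
    orientation mixtures.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
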