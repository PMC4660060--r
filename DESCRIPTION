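Package: xlbeads
Title: Coarse-Grained Integrative Modelling of Protein Complexes from
    Cross-Linking Mass Spectrometry Restraints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Determines the molecular architecture of multi-protein
    complexes from chemical cross-linking / mass spectrometry data.
    Proteins are represented as chains of spherical beads (ten residues
    per bead by default); cross-links become ambiguous upper-bound
    harmonic restraints on bead surface distances, combined with chain
    connectivity, excluded volume, localization-box and subcomplex
    connectivity terms under a two-fold symmetry constraint.
    Conformations are sampled by Metropolis Monte Carlo with parallel
    tempering (optionally in the well-tempered ensemble), and the
    resulting ensembles are analysed by greedy RMSD clustering,
    localization probability density maps, bead variability, restraint
    satisfaction, contact/macro-region maps and jackknife validation.
    Includes restraint-guided flexible docking onto a coarse-grained
    tubulin lattice, benchmarking of cross-link sets against reference
    atomic structures, and a synthetic-data generator that simulates
    cross-link observations from known bead-level structures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
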