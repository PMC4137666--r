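Package: coilstab
Title: Stability Analysis of Trimeric Coiled-Coil Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse the thermal stability of trimeric coiled-coil
    proteins such as bacterial lipoprotein-like alanine zippers. Builds ideal
    three-chain coiled-coil backbones from Crick parameters, assigns heptad
    registers and lipobox motifs, assigns pH-dependent protonation states,
    detects hydrogen bonds, salt bridges and intermonomer hydrophobic contacts
    with geometric cutoffs, computes RMSD/RMSF descriptors and neighbor-based
    decoy clustering, extracts melting temperatures from replica-temperature
    ladders, and reconstructs two-dimensional free-energy landscapes over
    helix content and hydrophobic contacts by multiple-histogram reweighting
    (WHAM). A synthetic replica-ensemble generator with a two-state melting
    model makes every stage testable without molecular-dynamics trajectories.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    Rcpp,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
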