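Package: braftools
Title: Conformational Descriptors and Dimer-Selectivity Analysis for BRAF Kinase Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structural analysis of BRAF V600E kinase monomers and dimers and
    their inhibitors. Computes kinase conformational descriptors (alpha-C helix
    position, DFG-motif C-alpha pseudo-dihedral, Lys483-Glu501 salt bridge),
    protein-ligand interaction fingerprints with KLIFS-style back-pocket
    occupancy, an empirical co-crystal-based classifier of inhibitor dimer
    selectivity, per-frame descriptor statistics for molecular-dynamics
    trajectories, and difference contact-network (community) analysis of apo
    versus holo ensembles. Includes a synthetic structure and trajectory
    generator so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    graphics,
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
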