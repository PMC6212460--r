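Package: cavitybind
Title: Trajectory Analysis of Ligand Binding in Buried Receptor Cavities
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to characterize ligand binding modes in buried protein
    cavities from molecular-dynamics trajectories: superposition-free dRMSD
    pose comparison against reference crystal poses, first-passage escape-time
    statistics with censoring across simulation replicas, polar orientation
    collective variables with solid-angle-reweighted probability maps,
    detection of water-exchange events through labelled entrance channels with
    flicker suppression, and GROMOS (Daura) RMSD-based conformational
    clustering. Includes readers and writers for PDB, GRO, multi-model PDB and
    DCD files, an atom-selection grammar, Kabsch least-squares superposition,
    and a seedable synthetic-data generator that emulates metastable ligand
    orientations, scheduled escape events and channelled water traffic so
    every analysis stage is testable without running molecular dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
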