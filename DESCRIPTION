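Package: ConfSel
Title: Conformation-Selection Analysis of Kinase Inhibitors by HDX-MS and NMR
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing conformation selection by ATP-competitive
    kinase inhibitors under a two-state (R/L) conformational-exchange model,
    developed around the ERK2 system. Simulates peptide-level
    hydrogen-deuterium exchange mass spectrometry (HDX-MS) uptake time
    courses and slow-exchange methyl HMQC peak pairs from an explicit
    forward model; computes centroid masses, in-exchange-corrected
    deuterium uptake, and the per-segment difference-AUC (dAUC) statistic;
    ranks and classifies inhibitor panels as R-state-selective,
    exchange-retaining, or intermediate; estimates R:L state populations
    and chemical-shift perturbations from peak tables; and measures
    structural geometry (Kabsch superposition, per-residue RMSD,
    halogen-to-ring-centroid distances) from PDB/mmCIF coordinates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
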