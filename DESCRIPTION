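Package: e2discharge
Title: MALDI-TOF E2 Ubiquitin Discharge Assay Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for intact-protein MALDI-TOF E2 ubiquitin
    discharge assays. Computes average masses of ubiquitin, its condensation
    adducts with small-molecule nucleophiles (acetyl-lysine, acetyl-serine,
    acetyl-threonine, glycerol, glucose) and a uniformly 15N-labeled internal
    standard; simulates linear-mode spectra for whole screening plates with
    known ground truth; detects peaks with a signal-to-noise gate, performs
    single-point internal recalibration on the 15N standard and matches peaks
    against a mass control list; converts peak areas into per-well discharge
    percentages and aggregates replicates into screen heatmaps and time
    courses; and classifies hydrophobic, ionic and cation-pi contacts at an
    E2~ubiquitin model interface from PDB coordinates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    bio3d,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mzR,
    signal,
    ggplot2,
    jsonlite,
    optparse
Config/testthat/edition: 3
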