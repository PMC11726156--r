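Package: fibril
Title: Geometry, Fold Comparison and Segment Composition Analysis for
    Amyloid Filament Polymorphs
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the downstream analysis of helically reconstructed
    amyloid filament models, motivated by the polymorph landscape of
    alpha-synuclein filaments from multiple system atrophy (MSA). Reads and
    writes atomic models (PDB/mmCIF), decomposes filament stacks into rungs
    and labelled protofilament folds, represents helical screw symmetry
    (twist/rise, crossover distance), fits screw parameters from adjacent
    rungs, superposes folds (Kabsch) to compute all-atom RMSD and
    per-residue C-alpha displacement profiles, detects inter-rung steric
    clashes in hybrid mixed-polymorph cofilament models, and analyses
    per-filament composition of classified cryo-EM segments (predominance
    categories, histograms, strongly mixed filament counts). Ships synthetic
    generators for toy filaments with known helical parameters and for
    segment classification tables with a stated mixture and
    misclassification model, together with analytic expectations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
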