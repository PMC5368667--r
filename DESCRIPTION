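Package: vhmature
Title: Affinity/Stability Trade-Off Analysis for Antibody VH Affinity Maturation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for characterizing affinity/stability trade-offs
    accumulated during affinity maturation of autonomous antibody heavy-chain
    variable (VH) domains. Fits yeast-surface-display titrations to a
    saturation-plus-nonspecific fluorescence binding model to estimate
    equilibrium association constants, extracts apparent melting temperatures
    from circular dichroism thermal scans via linear folded/unfolded baselines
    and the fraction-folded transform, classifies each mutation in a
    Kabat-numbered mutation lineage as affinity-enhancing/neutral/reducing and
    stabilizing/neutral/destabilizing from replicate-level two-sample t-tests,
    and maps surface hydrophobicity from multi-frame structures by counting
    probe particles near each heavy atom, with greedy RMSD clustering of
    conformations. Synthetic-data generators with known ground truth make every
    stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
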