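Package: rnadynr
Title: Validation and Free-Energy Analysis of Protein-RNA Structure Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for multi-model coordinate ensembles of
    protein-RNA complexes, as produced by molecular dynamics or NMR.
    Back-calculates NOE effective distances with r^-6 ensemble averaging and
    scores restraint violations; selects NOE-adapted representative ensembles
    by frame filtering and k-means clustering; measures hydrogen-bond and
    stacking occupancies with geometric criteria; profiles backbone plasticity
    through circular dispersion of Ramachandran angle sums with
    fluctuation/transition tagging and dihedral-histogram conformational
    entropy; computes DRID and fraction-of-native-contact collective variables
    with Gaussian kernel density maps of sampling coverage; plans replica
    exchange with solute tempering (lambda ladders and partial-scaling
    regions); and estimates free-energy differences from bidirectional
    non-equilibrium work values with a Crooks-theorem maximum-likelihood
    estimator and thermodynamic-cycle differences. Includes seeded synthetic
    ensemble generators with planted ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    MASS,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
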