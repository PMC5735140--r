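Package: limbquant
Title: Quantification Pipeline for Longitudinal Intravital Bone-Marrow
    Microendoscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for longitudinal intravital two-photon
    microendoscopy of the femoral bone marrow and accompanying micro-CT
    bone morphometry. Provides seeded synthetic-scene generators with
    known ground truth (vessel remodeling scenes, motile B-lineage cell
    movies, photoactivation series, micro-CT phantoms, bead stacks),
    point-spread-function and signal-to-noise characterization, 3D vessel
    segmentation with local-thickness diameter mapping and a normalized
    volume-change remodeling statistic stratified by vessel diameter,
    cell detection/tracking/motility metrics with volume-based
    classification of B cells versus plasma cells, photoactivated-GFP
    decay and positional-stability analysis, two-Gaussian cortical
    thickness fitting and bone volume/surface morphometry, and tabular
    post-surgical welfare analytics (clinical scores, activity
    normalization).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    igraph,
    minpack.lm,
    rlang,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
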