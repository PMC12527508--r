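Package: fcnm
Title: Functional Connectivity Network Mapping of Reported Brain Coordinates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maps tables of reported peak brain coordinates to
    disorder-susceptibility networks via resting-state functional
    connectivity in a normative cohort. Builds merged spherical seed
    masks from published peak coordinates (with Talairach-to-MNI
    harmonisation), performs temporal cleaning of 4D BOLD series
    (framewise displacement, Friston-24 and tissue nuisance regression,
    spike regressors, 0.01-0.1 Hz band-pass), computes seed-to-whole-brain
    Fisher-z correlation maps per subject, applies voxelwise one-sample
    t-tests with Benjamini-Hochberg false discovery rate binarisation,
    overlays contrasts into probability maps thresholded into network
    masks, and quantifies network similarity (Dice) and composition
    relative to a canonical network atlas. Includes a seeded synthetic-data
    generator with planted networks so that every stage is verifiable by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    graphics,
    tools,
    utils,
    parallel
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
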