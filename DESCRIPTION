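Package: irifdose
Title: Biodosimetry of High-LET Ion Exposure from Radiation-Induced Focus Counting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates absorbed dose from counts of ionizing-radiation-induced
    foci (IRIF) along heavy-ion tracks in super-resolution image stacks. A
    track-structure toy simulator draws double-strand-break (DSB) positions
    along straight ion chords through a spherical nucleus; DSBs are grouped
    into finite-size clusters (single-linkage at the detectable focus size) to
    build a monotone linear-cluster-density versus linear-energy-transfer
    (LET) calibration curve with a 68 percent band, which is inverted to read
    LET off a measured linear IRIF density. Dose follows from fluence and LET,
    for single and mixed particle fields, with the linear error propagation
    used in practice. Imaging utilities measure focus sizes by Pearson image
    autocorrelation, detect foci in 3D stacks, gate detections by
    colocalization with a second marker, and compute per-volume and per-track
    IRIF statistics.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
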