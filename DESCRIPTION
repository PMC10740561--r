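Package: ionpaint
Title: Paint Irradiation Planning for Focused Heavy-Ion Microbeams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Plans uniform "paint" irradiation of microscope-defined regions
    with a focused heavy-ion microbeam. Converts a region of interest (drawn
    shapes or binarized fluorescence images) plus an absorbed-dose
    prescription into a scanner-ready list of discrete ion hit coordinates,
    using stratified ("even random") spatial sampling so that the dose is
    deposited as uniformly as the natural-number ion count allows. Includes
    dose/fluence/ion-count dosimetry for high-LET ions, a virtual CR-39
    track-detector simulator (beam-spot jitter, etch-pit rendering, quadrat
    dispersion statistics, contour-expansion measurement), plan-file and
    scan-list I/O with scanner voltage calibration, and deterministic
    synthetic fixtures (circle, dose-graded logo, nematode organ shapes).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    withr,
    yaml,
    jsonlite,
    png,
    tiff,
    mgcv,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
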