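Package: chapsta
Title: Subtomogram Averaging and State Census of Chaperonin Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale cryo-electron tomography pipeline for quantifying
    barrel-shaped chaperonin (GroEL-GroES) complexes in cells: missing-wedge
    constrained cross-correlation template matching, subtomogram alignment and
    averaging with Cn/Dn symmetry, gold-standard Fourier shell correlation
    resolution estimation, simulated-annealing multireference classification
    with consensus retention, and a seven-state census of conformation and
    substrate occupancy.  Ships a parametric phantom simulator that plants
    ground-truth particles into noisy missing-wedge tomograms so that every
    stage can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
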