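Package: epimech
Title: Mechanical Analysis of Epithelial Monolayers: Cell-Cycle Phase Calling,
    Traction and Monolayer Stress Microscopy, PIV, and FRET Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for the quantitative analysis of epithelial
    monolayer mechanics and cell-cycle dynamics. Implements FUCCI4 cell-cycle
    phase-length calling from per-cell fluorescence traces by change-point
    detection, single-pass cross-correlation particle image velocimetry,
    forward and inverse finite-thickness Fourier traction force microscopy on
    soft elastic substrates, monolayer stress microscopy (recovery of the
    in-sheet line-tension tensor by force balance), ratiometric FRET
    tension-sensor quantification at cell-cell contacts, and a cohort
    statistics layer (per-cell intensity normalization, experiment-level
    paired tests, density classification, mitotic-fraction time courses).
    Every analysis stage is paired with a synthetic-data generator that
    emulates the statistical structure of monolayer imaging data with known
    ground truth, so the whole pipeline is testable without any raw images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
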