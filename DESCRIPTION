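Package: wormwound
Title: Quantification of Wound-Healing Dynamics in C. elegans Epidermal Time-Lapse Movies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-quantification pipeline for laser-wound healing in the
    C. elegans adult epidermis (hyp7), built around single-channel
    fluorescence time-lapse stacks with known pixel size and frame interval.
    Provides microtubule plus-end (EB1) comet detection and linking with
    wound-referenced directionality statistics, temporal-median background
    subtraction and translational drift correction, wound-centred radial
    profiles, normalized anterior-posterior kymographs and two-phase
    ring-closure velocimetry, Huang automatic thresholding of the actin ring,
    structure-tensor orientation mapping with wound-referenced angles over
    annular sectors, recruitment (integrated and mean intensity) traces, and
    a calibrated synthetic-movie generator that emits ground truth for every
    stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    tiff,
    png,
    jsonlite,
    EBImage,
    stats,
    utils,
    grDevices
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
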