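Package: denudakit
Title: Simulated Robotic Oocyte Denudation: Vision, Calibration and Flow Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational core of a robotic oocyte-denudation workstation,
    exercised entirely on synthetic microscopy scenes. Provides micropipette
    tip localization and substrate-contact detection, oocyte and cumulus-cell
    recognition with least-squares circle fitting and a zona-pellucida
    attachment rule, automated stage-camera misalignment calibration from
    image-mosaic registration, an aspiration-flow dynamics model yielding the
    admissible flow-rate window between cumulus adhesion and the physiological
    shear limit, in-pipette oocyte tracking with a stop-flow guard, and a
    deterministic simulator of the full four-well denudation protocol.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    jsonlite,
    stats
Suggests:
    tiff,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
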