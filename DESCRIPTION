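Package: dmfsimoa
Title: Digital-Microfluidic Sample Processing Simulators for Single-Molecule
    Bead Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Physics-based simulators and statistics for digital-microfluidic
    (DMF) front-end processing of single-molecule array (Simoa) bead assays.
    Implements the electrowetting droplet-retention pressure model
    (Young-Lippmann force, densifying-electrode pressure imbalance, reservoir
    Laplace pressure), a capacitance-feedback closed-loop loading controller
    with a rolling stability index and load/split/waste-removal state machine,
    simulators of passive, parallel and stepwise sample-loading strategies
    with magnetic-bead retention accounting (Stokes drag versus magnetic
    trapping, Darcy/Washburn wicking into absorbers), the Poisson statistics
    of digital single-molecule counting (expected molecule numbers,
    molecule-to-bead distribution, average-enzymes-per-bead estimation,
    bead-retention percentages), and a synthetic brightfield bead-image
    generator with a matching bead-counting pipeline. No hardware or external
    data is required: all inputs are generated in-package.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    withr,
    EBImage,
    tiff
Suggests:
    testthat (>= 3.0.0),
    png
Config/testthat/edition: 3
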