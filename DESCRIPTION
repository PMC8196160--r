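Package: warpmic
Title: Wavelength-Alternating Resonant Pressure Microscopy Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of wavelength-alternating resonant
    pressure (WARP) microscopy, an interferometric method that maps
    nanometre-scale deformations of an elastic optical microcavity induced
    by cellular forces. Provides a closed-form optical model of the
    low-finesse cavity, a synthetic scene generator that renders
    dual-wavelength interference image stacks with ground-truth
    displacement fields, the WARP reconstruction algorithm
    (sum/difference/division imaging, sub-pixel fringe counting and
    lookup-table calibration), a wavelength-scanning interference oracle
    for validation, and downstream mechanics and dynamics analyses:
    flat-punch force estimation for podosome-scale protrusions, podosome
    segmentation and force-area statistics, indented-volume contraction
    traces, peak detection and contraction variability metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    withr,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
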