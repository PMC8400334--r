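Package: kelpscan
Title: Real-Time Foreign-Object Detection on Seaweed Sheets from VNIR
    Hyperspectral Line Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting foreign objects (shrimp shell, plastic,
    insects, thread) on dried seaweed sheets imaged by a push-broom VNIR
    (400-1000 nm) hyperspectral camera over a conveyor belt. Implements
    ENVI raster input/output, dark-current and white-reference calibration
    with per-pixel percent normalization (Per-Norm), max normalization and
    reflectance conversion, spectral binning by band decimation, a
    two-stage detector (two-band subtraction segmentation followed by
    per-band standardization envelope inspection), a spectral angle mapper
    (SAM) multi-class baseline, a synthetic push-broom scene generator
    with ground-truth masks, and sheet-level confusion metrics plus
    data-rate calculators for throughput planning.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    yaml,
    kernlab
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    png
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
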