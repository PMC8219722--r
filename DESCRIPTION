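Package: AcsaScan
Title: Semi-Automatic Measurement of Muscle Anatomical Cross-Sectional
    Area in Panoramic Ultrasound Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Measures the anatomical cross-sectional area (ACSA) of the
    rectus femoris and vastus lateralis muscles in extended-field-of-view
    (EFOV) B-mode ultrasound images. Images are calibrated from a manual
    or automatically detected scale line, aponeuroses are enhanced with a
    Hessian-based tubeness filter and Canny edge detection, and the muscle
    boundary is traced by casting scanning beams from interior starting
    points; the clockwise-sorted hit polygon yields the area in square
    centimetres. Also provides the reliability battery used to validate
    such measurements (consecutive-pairwise intraclass correlation,
    standard error of measurement, minimal detectable change,
    Bland-Altman limits of agreement, standardized mean bias) and a
    synthetic speckle-phantom generator with analytic ground truth so the
    whole pipeline is testable without real scans.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    EBImage,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AcsaScan-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'filters.R'
    'preprocess.R'
    'outline.R'
    'acsa.R'
    'io.R'
    'scaling.R'
    'batch.R'
    'methods.R'
    'utils-geometry.R'
    'phantom.R'
    'stats.R'
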