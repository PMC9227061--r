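Package: platescope
Title: Simulated Multiwell Imaging Station: Autofocus, Cell Phenotyping,
    Motility and Automation Scripting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A complete software stack for an automated multiwell
    bright-field imaging station, runnable entirely against a simulated
    hardware backend. Maps well addresses of 12-, 24- and 96-well plates on
    a two-plate holder to stage coordinates; simulates a 3-axis stage with
    homing noise, a peristaltic pump with relative volume error, per-well
    RGBW LEDs and a camera imaging a liquid column of motile cells;
    performs two-phase coarse-to-fine autofocus using the variance of the
    Laplacian as focus measure; segments and measures cells by
    thresholding, morphological closing and contour analysis with
    micrometer calibration; quantifies single-cell and whole-field motility
    by pyramidal Lucas-Kanade optical flow; and validates, time-estimates
    and executes JSON automation scripts describing sampling, illumination
    and capture sequences. A synthetic-fixture generator produces
    calibration slides, micrographs, focus stacks and motility videos with
    full ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
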