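Package: nucirr
Title: Nuclear Membrane Irregularity Scoring for Cervical Cytology
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Quantifies nuclear membrane irregularity of single cervical
    squamous epithelial cells. Implements two radial-profile scores: a
    penalty-driven smoothing analysis that bins normalized deviations of
    the contour's radial profile from a circular moving average and
    weights the bins with linear, quadratic, or cubic penalties, and a
    residual-based analysis that summarizes absolute deviations of the
    radial profile from its mean or median. Also provides the classic
    comparison metrics (radial asymmetry, shape factor, rim difference),
    a gradient-statistics nucleus segmentation pipeline, a synthetic
    nucleus generator emulating NILM, LSIL, and HSIL contour morphology,
    and a Friedman test with Holm, Shaffer, and Bergmann-Hommel post-hoc
    pairwise comparisons.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    png,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    tiff,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
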