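Package: wallmark
Title: Landmark-Based Analysis of Bacterial Cell Wall Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing bacterial cell wall growth by tracing
    wall-anchored protein complexes (such as flagellar motors) as fluorescent
    landmarks in time-lapse microscopy. Provides a ground-truthed simulator of
    growing and dividing spherocylindrical cells with wall-anchored landmarks,
    subpixel spot localization and cell-geometry extraction from image stacks,
    kinematic analysis of landmark traces (inert-zone changepoint fitting,
    homogeneous axial expansion and the per-length growth rate), and the
    Bernoulli shift map model for the cross-generation partitioning of
    wall-anchored proteins.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    EBImage,
    tiff,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
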