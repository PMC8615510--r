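Package: tecquant
Title: Quantification Toolkit for Tissue-Engineered Micrometastasis Assays
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Image and curve quantification for tissue-engineered
    micrometastasis models: H&E colour deconvolution with convex-hull
    circularity morphotyping and compartment-resolved invasion depth,
    ridge-detection skeletonization of chorioallantoic-membrane (CAM)
    vasculature with branch-length density per region of interest,
    logistic growth modelling of viability time courses, and weighted
    Hill dose-response pharmacodynamics with EC50/IC50 extraction.
    Includes ground-truthed synthetic-data generators (stained sections,
    vessel trees, viability curves, dose-response tables) so every stage
    of the pipeline can be validated against analytic truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    EBImage,
    minpack.lm,
    pracma,
    jsonlite,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Software, CellBiology, Visualization, Preprocessing
RoxygenNote: 7.3.3
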