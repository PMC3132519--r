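Package: endoseg
Title: Pixel-Wise SVM Segmentation of Thin Endothelial Cell Boundaries
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segmentation of thin, dark, silver-stained endothelial cell
    boundaries in light-microscopy monolayer images. Each pixel is mapped to a
    33-dimensional feature vector (3x3 intensity patch, 3x3 patch of an
    orientation-dominance vector field built from band-pass filters, and six
    patch statistics) and classified as boundary or background by a support
    vector machine. Includes classical baselines (Otsu and Kittler-Illingworth
    minimum-error thresholding, Canny edge detection), minimum-redundancy
    maximum-relevance (mRMR) feature ranking, an intensity mixture-model
    analysis with quadratic illumination correction, ROC and accuracy
    evaluation machinery, and a synthetic monolayer phantom generator with
    exact ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    e1071,
    EBImage,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: CellBiology, Segmentation, Classification, SupportVectorMachine
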