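Package: afmicell
Title: Label-Free Single-Cell Phenotyping from Autofluorescence
    Multispectral Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for 47-channel autofluorescence
    multispectral imaging of cultured mesenchymal stromal cells.
    Provides calibration and preprocessing of spectral data cubes
    (cosmic-ray removal, low-rank plus wavelet denoising, background
    subtraction, flat-field correction, reference-fluid calibration),
    per-cell intensity, texture and morphology feature extraction,
    assay gating, a classification stack (minimum-redundancy
    maximum-relevance feature selection, PCA followed by a regularised
    linear discriminant embedding, ADASYN rebalancing, SVM and LDA
    classifiers with cross-validated ROC analysis), a coarse
    k-nearest-neighbour predictor of remaining population doublings,
    and a synthetic-data generator that emulates the statistical
    structure of the imaging data for testing and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    tiff,
    jsonlite,
    yaml,
    e1071,
    MASS,
    pROC,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
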