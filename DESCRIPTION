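Package: axonwrap
Title: Quantification of 3D Myelin Wrapping on Artificial-Axon Micropillar Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for artificial-axon (AA) myelination assays:
    segmentation of multi-channel confocal z-stacks of vertical micropillar
    arrays, per-axon circumferential wrap-fraction scoring via outline/overlap
    masks, full-wrap classification and the wrapping index, myelin sheath
    length distributions, and four-parameter logistic dose-response fitting
    with EC50, efficacy, relative efficacy and compound ranking. Includes a
    synthetic image and dose-series generator with exact ground truth so the
    whole pipeline is testable without raw microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
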