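Package: panelseg
Title: Compound-Figure Panel Classification and Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Classifies biomedical figures as single-panel, regular
    multi-panel, or irregular multi-panel and splits multi-panel figures
    into their component sub-images. Regular layouts (uniform white
    gutters or straight separators) are segmented by recursive
    projection-profile analysis; irregular layouts (stitched mosaics,
    non-uniform gaps) by Otsu thresholding, morphological closing and
    connected-component analysis. Includes a ground-truthed synthetic
    montage generator, the overlap-based precision/recall/F1 evaluation
    protocol used in figure-separation studies, and a command-line
    interface for batch preprocessing in content-based medical image
    retrieval pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    png,
    yaml
Suggests:
    jpeg,
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
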