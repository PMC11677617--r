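Package: spheroVis
Title: Image-Based Viability Scoring of Tumor Spheroids in Microwell Devices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies drug response of tumor spheroids cultured in
    microwell arrays from multichannel microscopy images. Segments spheroids
    in bright-field and calcein AM fluorescence channels, measures maximum,
    minimum and mean Feret diameters, applies a binary intensity threshold to
    derive the binary area fraction (BAF) of the calcein region of interest,
    and combines calcein-derived sphere volume with BAF into the IMVIS
    viability index. Includes a seeded synthetic scene generator with exact
    ground truth that emulates osteosarcoma- and chondrosarcoma-like
    doxorubicin phenotypes, plus nonparametric (Mann-Whitney U) dose-group
    comparisons with mean +/- SEM summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    tiff,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
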