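Package: ecmorient
Title: Quantification of Tumor-Induced Collagen Network Orientation and
    Endothelial Spheroid Response
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Image-analysis pipeline for quantifying remote extracellular
    matrix (ECM) remodelling around tumor spheroids grown in 3D collagen
    gels.  Detects fibrillar structures in reflection-microscopy images,
    scores each fiber by the cosine-square of its angle to the radial
    direction from the tumor spheroid, bins the statistic by distance from
    the spheroid edge, fits a single exponential plateauing at the random
    baseline 0.5 and derives the integrated orientation (Y0 - 0.5) * L0 and
    the orientation extent.  Also segments tumor spheroids from DIC-like
    images, counts nuclei in z-stacks by watershed, and scores endothelial
    spheroid masks for direction toward the tumor, elongation and their
    product.  A ground-truthed synthetic-scene generator makes every stage
    verifiable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
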