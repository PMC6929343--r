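Package: anchor3d
Title: Automated 3D Modelling of Monogenean Haptoral Anchors from 2D
    Illustrations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated pipeline that turns 2D landmark-annotated
    illustrations of monogenean haptoral anchors into deformed 3D models.
    Synthetic 96x96 grayscale training illustrations are produced by
    morphing parametric anchor outlines (34 ordered point primitives) and
    applying random similarity transforms; records are kept in an embedded
    JSON Lines document store; a multilayer perceptron (9216-512-128-68,
    ReLU, SGD with Nesterov momentum, mean squared error) regresses the 34
    landmark positions from pixels; predicted landmarks drive a
    mean-value-coordinate deformation of a generic watertight anchor mesh,
    exported as Wavefront OBJ or ASCII PLY; predicted and control landmark
    distributions are compared through five-number (box plot) summaries
    and point-wise error metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    optparse,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
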