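Package: stemleaf3d
Title: Plant Stem and Leaf Segmentation and Trait Extraction from 3D Point Clouds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for 3D plant phenotyping from point clouds: extraction of
    dense point clouds from implicit radiance fields by expected-depth volume
    rendering, point-cloud preprocessing (colour-threshold ground removal,
    statistical outlier filtering, farthest point sampling, normal estimation),
    a lightweight encoder-decoder point-cloud semantic segmentation network
    with global-local set abstraction encoder stages and edge-aware feature
    propagation decoder stages trained with a polynomial focal loss, and
    geometric extraction of stem height, stem diameter, leaf length and leaf
    width from segmented clouds.  A procedural generator of labelled plants
    with analytic ground truth makes every stage testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
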