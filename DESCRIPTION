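Package: berry3d
Title: 3D Point-Cloud Morphometry of Strawberry Shape Uniformity
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies strawberry fruit shape uniformity from 3D point
    clouds produced by multi-view (structure-from-motion) reconstruction.
    Provides PLY input/output with per-point colour, a pre-processing chain
    that isolates the berry body (hue-based denoising, translation to the
    origin, principal-axis alignment, body/holder segmentation and metric
    scale standardisation against a reference holder of known height), and
    eight shape-uniformity metrics: coefficient of variation and max/min
    ratio of rotational side-view silhouette areas, dispersion of silhouette
    principal orientations, bounding-box aspect ratio, circularity and
    centre-axis straightness of horizontal cross-sections, and coefficient
    of variation and max/min ratio of surface principal curvatures estimated
    by local quadric fitting after moving-least-squares smoothing. A
    parametric synthetic-berry generator with ground-truth labels makes the
    whole pipeline testable without imaging hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, grDevices, utils, tools, jsonlite, yaml, Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
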