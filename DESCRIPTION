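Package: mitoseg
Title: Three-Step Segmentation of Mitochondria in Serial Block-Face EM Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Automatic segmentation of mitochondria in anisotropic serial
    block-face scanning electron microscopy (SBFSEM) volumes using a
    three-step pipeline: a random-forest patch classifier on raw 2D pixel
    patches produces a per-voxel probability map; isocontours of the map are
    extracted, described by seven geometric and intensity features, paired
    across adjacent planes and filtered by a second random-forest classifier;
    surviving salient contours seed a 3D geodesic active contour level set
    evolved on an edge potential derived from the probability map.  Includes
    stack input/output with physical voxel spacing, a synthetic EM phantom
    generator with ground truth, pixel-level ROC evaluation, and an
    error-weighted threshold selection procedure, so the whole pipeline can
    be trained, applied and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ranger,
    stats,
    grDevices,
    graphics,
    tiff,
    png,
    yaml,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    pROC,
    jsonlite
Config/testthat/edition: 3
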