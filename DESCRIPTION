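Package: meristemorph
Title: 2.5D Morphometrics of the Shoot Apical Meristem Epidermis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative 2.5D image analysis of the shoot apical meristem
    (SAM) epidermis from confocal-like image stacks: surface extraction as a
    heightmap mesh, projection of cell-wall stain, seeded watershed cell
    segmentation on the curved surface, discrete Gaussian curvature at a
    fixed neighborhood radius, curvature-based delimitation of the meristem
    region, topological zonation (central and peripheral zones by cell-graph
    distance from the summit cell), per-cell size and number quantification,
    depth-band projection of fluorescent reporter signal onto the cellular
    mesh, and group statistics (one-way ANOVA, Tukey HSD, compact letter
    display). Includes a calibrated synthetic apex generator producing
    meshes, segmentations and image stacks with full ground truth for the
    vegetative, domed and inflorescence stages of floral transition, so that
    the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    tiff,
    png
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
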