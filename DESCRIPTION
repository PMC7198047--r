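Package: woundmetrics
Title: Contactless 3D Wound Measurement, Tissue Mapping and Projector-Based
    Augmented-Reality Follow-Up
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the clinical parameters of chronic wounds (maximal
    depth, perimeter, 3D and projected area, main axes, volume) from a
    stereo-derived coloured 3D point cloud. Provides pinhole/stereo/projector
    geometry with normalized-cross-correlation matching, semi-automatic
    Chan-Vese contour refinement, self-organizing-map quad-mesh surface
    reconstruction, alpha-shape area and plane-capped volume estimation,
    seeded SLIC plus k-means tissue classification in CIELAB chroma,
    fiducial-based rigid registration between visits with synthesis of the
    projector overlay image, measurement-reliability statistics (accuracy,
    coefficient of variation, ICC(2,1), ANOVA repeatability), and synthetic
    wound phantoms with analytic ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    jsonlite,
    yaml,
    EBImage,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
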