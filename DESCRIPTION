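Package: carrotshape
Title: Shape-Based Grading of Carrot Silhouettes by Discriminant Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Machine-vision grading of carrots into regular and irregular
    shape classes from single-object RGB images. Provides blue-channel
    segmentation into a clean binary silhouette, classical region
    descriptors (area, perimeter, roundness, compactness, elongation,
    eccentricity, extent), partitioned centroid and width nonhomogeneity
    descriptors computed over seven slices along the principal axis, a
    root-count feature for forked roots, Gaussian linear and quadratic
    discriminant classifiers with confusion-matrix evaluation and
    cross-validation, a cross-validation wrapper for sequential forward
    feature selection, and a parametric generator of ground-truthed
    synthetic carrot silhouettes for testing the full pipeline end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
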