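Package: spotweed
Title: Seedling-Avoiding Trajectory Planning and Weed Segmentation for
    Precision Spot Spraying
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computational core of a precision weeding workflow for
    row crops: excess-green (2G-R-B) weed segmentation with Otsu
    thresholding, morphological cleanup and connected-domain area
    filtering; box-level detection evaluation (IoU, precision, recall,
    average precision); an arch-shaped ("inverted-U") seedling-avoidance
    trajectory built from cubic Bezier transitions and optimized by
    particle swarm search with an adaptive step factor; delta
    parallel-arm inverse kinematics with equal arc-length trajectory
    discretization; and seeded synthetic scene generators (field images
    with ground truth, 3-D spray scenes) so the whole chain is testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    jsonlite,
    png,
    graphics,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
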