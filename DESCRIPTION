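Package: sproutpol
Title: Quantification of Directed Endothelial Migration, Front-Rear
    Polarity and 2-D Vessel Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify directed cell migration and front-rear
    polarity in scratch-wound assays and 2-D vessel morphometry in
    retinal/brain vasculature images. Includes centroid detection and
    greedy nearest-neighbour track linking with physical calibration,
    per-cell migration statistics (speed, net displacement, directional
    persistence, angular sector fractions), nuclear shape and organelle
    (Golgi/MTOC) polarization angle measurements, skeleton-based branch
    point counting, vascular density and intensity normalization, and
    differential-expression overlap/sign-concordance logic. A synthetic
    data module generates trajectories, label images, wound series,
    vessel networks and paired DEG tables with known ground truth so
    every estimator ships with recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    graphics,
    jsonlite,
    stats,
    tiff,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
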