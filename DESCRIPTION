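Package: canopymetrics
Title: Whole-Tree Structural Metrics from Terrestrial LiDAR Point Clouds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts whole-tree structural metrics from single-tree
    terrestrial laser scanning (TLS) point clouds scanned leaf-off: statistical
    outlier removal by mean k-nearest-neighbour distance, tree location and
    diameter at breast height (DBH) by least-squares circle fitting to
    horizontal slices, crown start detection by the relative jump of fitted
    slice radii, tree height, crown radii in 72 azimuthal directions (flat and
    in 2 m height bands), maximum crown diameter, and convex-hull crown
    projection area.  Also parses quantitative structure model (QSM) cylinder
    tables, builds the directed parent-child cylinder graph, computes woody
    volume, and audits cylinder fits by point-to-cylinder distances.  Includes
    a seeded procedural generator of leaf-off tree point clouds with exact
    ground truth for benchmarking, project-to-global affine coordinate
    transforms, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    optparse,
    purrr,
    RANN,
    readr,
    grDevices,
    stats,
    utils,
    rlang,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
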