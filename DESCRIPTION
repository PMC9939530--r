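Package: crowngf3d
Title: Volume-Based Gap Fraction of Tree Crowns from Terrestrial Laser Scanning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes the volume-based gap fraction (crown porosity) of tree
    crowns from terrestrial laser scanning point clouds by treating the crown
    as a porous medium. Points are classified into wood and leaves from local
    covariance eigen-features, individual leaves are segmented via great-circle
    centre detection followed by geodesic region growing and DBSCAN, each leaf
    is enclosed in a hexagonal prism whose height is the equivalent leaf
    thickness (the point extent along the leaf normal, capturing curl and
    droop), branch segments are fitted with cylinders, and the crown volume is
    obtained from a 3D alpha shape (convex hull at alpha = infinity). The gap
    fraction is one minus the ratio of total leaf and wood volume to crown
    volume. Includes a parametric synthetic-tree generator emulating TLS
    sampling with analytic ground truth, plus hemispherical-photograph,
    voxel-occupancy and Beer-Lambert baseline estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RANN,
    MASS,
    e1071,
    minpack.lm,
    igraph,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
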