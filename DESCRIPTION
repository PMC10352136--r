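Package: coatlattice
Title: Helical Lattice Analysis of Membrane Tubule Coats from Subtomogram Coordinates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coordinate-level analysis of helical protein coats on membrane
    tubules, as produced by cryo-electron tomography and subtomogram
    averaging. Provides tube-axis splines with rotation-minimizing frames,
    cylinder unrolling, helix parametrization (radius, pitch, number of
    starts, handedness), lattice-guided subbox pose generation,
    cross-correlation driven coordinate deduplication, four-criterion
    outlier exclusion, neighborhood-plot lattice-vector estimation by
    k-means, helical symmetry expansion of atomic models, Shrake-Rupley
    solvent accessible surface areas with interface burial metrics, and
    Taubin circle fits for BAR-domain curvature. A synthetic tubule-lattice
    generator supplies ground truth for every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    graphics,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    bio3d,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
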