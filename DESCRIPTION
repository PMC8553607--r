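Package: volgrid
Title: Volumetric Analysis of Grid-Cell Firing Fields in Three Dimensions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the three-dimensional organisation of grid-cell
    firing fields recorded while animals explore volumetric environments such as
    climbing lattices. Provides adaptive-binned and histogram volumetric firing-rate
    maps, masked 3D spatial autocorrelation with anisotropy correction, hexagonal and
    square gridness scores, the oblique-plane (planar-symmetry) analysis with
    close-packing structure scores for FCC, HCP, columnar and random field
    configurations, 3D field detection with shape, orientation and spacing statistics,
    and the shuffle-based null procedures used to assess them. A synthetic-data module
    generates close-packed field arrangements, lattice-constrained trajectories and
    inhomogeneous-Poisson spike trains so the full pipeline can be exercised without
    recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
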