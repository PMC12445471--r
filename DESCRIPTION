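Package: laminardev
Title: Depth-Resolved Cortical Maturation Trajectories
Version: 0.1.0
Authors@R:
    person("Laminar", "Dev Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for depth-resolved analysis of cortical maturation from
    parcel-level myelin-sensitive imaging measures (such as the T1w/T2w
    ratio). Provides equi-volume cortical depth binning from local column
    geometry, geodesic-distance proxies for the sensorimotor-to-association
    cortical hierarchy on triangulated surface meshes, reference-region
    ratio calibration and aggregation, penalized-spline (GAM) developmental
    trajectory fitting with REML smoothness selection, simultaneous
    derivative confidence bands and plateau-age detection, and a
    cross-depth / cross-hierarchy / cross-species comparison layer. A
    synthetic cortical data generator with known ground-truth maturational
    structure (cross-sectional human-like and longitudinal macaque-like
    designs) makes the full pipeline testable without any imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    mgcv,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
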