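Package: hullbsp
Title: Body Segment Parameters from Convex Hulls of Skeletal Meshes
Version: 0.1.0
Authors@R:
    person("hullbsp", "maintainers", email = "maintainers@hullbsp.org",
           role = c("aut", "cre"))
Description: Estimation of mammalian body segment parameters (mass, centre
    of mass and inertial tensor) from convex hulls of skeletal segment
    meshes. Provides exact polyhedral mass-property integrals for
    watertight triangle meshes, three-dimensional convex hulling, planar
    slicing of elongate segments, a bundled calibration table converting
    naive hull parameters to soft-tissue predictions, and a regression
    framework (ordinary and phylogenetic generalized least squares under
    Brownian motion, with AIC selection and leave-one-out
    cross-validation) for fitting new calibration tables from paired
    hull/soft-tissue datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
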