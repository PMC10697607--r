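Package: ctenoswim
Title: Reduced-Order Simulation of Ctenophore Metachronal Swimming
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A three-dimensional self-propelled rigid-body model of
    metachronal drag-based paddling in ctenophores (comb jellies). The
    animal is a neutrally buoyant spheroid propelled by eight rows of
    oscillating flat plates (ctenes) whose tips trace temporally and
    spatially asymmetric elliptical paths with metachronal phase lags.
    Quasi-steady blade-element hydrodynamics at intermediate Reynolds
    numbers supply the propulsive, drag, added-mass and rotational
    resistance terms. The package provides the appendage control
    strategies (turning modes, frequency sweeps, independent row
    subsets, frequency-schedule replay), maneuverability and agility
    metrics (normalized radius of curvature and mean speed), trajectory
    canonicalization, voxelized motor-volume estimation, and a
    command-line driver.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
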