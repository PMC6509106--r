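Package: rootflux
Title: Functional-Structural Root-System Modelling of Water Uptake and
    Tracer Transport
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Couples explicit three-dimensional root-system architectures
    with a voxel-grid Richards solver for variably saturated soil water
    flow, a Doussan-type xylem network model for root water uptake, and
    Lagrangian random-walk particle tracking for the transport of a
    conservative, root-excluded tracer. Includes a stochastic generator of
    lupin-like root architectures and experiment timelines, a virtual-MRI
    observation operator, RMSE-based grid-search inversion of root radial
    and axial hydraulic properties with local refinement and sensitivity
    cross-sections, and water-uptake proxy analyses (tracer accumulation
    and water depletion against simulated uptake density).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
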