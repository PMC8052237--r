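Package: rhinoflow
Title: Virtual Rhinomanometry from Voxelized Airways with a Lattice Boltzmann Solver
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparing clinical active anterior rhinomanometry (AAR)
    with flow simulations on voxelized nasal airway geometries. Provides
    synthetic nasal-like voxel phantoms and Rohrer-model pressure-flow
    generators, Hounsfield-threshold air-space segmentation with automatic
    nasal-tip detection and probe placement, a D3Q19 lattice Boltzmann solver
    (BGK collision with optional Smagorinsky large-eddy closure) that produces
    pressure fields at prescribed flow rates, digitization of plotted
    rhinomanometry curves by RGB thresholding and windowed discretization,
    flow-binned curve assembly with nasal resistance at a 150 Pa pressure
    drop, and log-scale Bland-Altman agreement statistics with
    factor-adjusted correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    png,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
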