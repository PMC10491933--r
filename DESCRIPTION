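Package: vesselqpi
Title: Vessel Morphometry from Simulated Quantitative Phase Imaging
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for quantitative phase imaging of
    cerebral blood vessels. Generates synthetic refractive-index phantoms of
    tubular vessels (walls, lumens, blood-cell inclusions, wall breaks, fiber
    structures), forward-simulates four-direction differential phase contrast
    (DPC) acquisition with photon noise, recovers phase by Tikhonov-regularized
    transfer-function deconvolution, converts phase to refractive index, and
    quantifies vessel morphology: wall thickness distributions, lumen diameter,
    percent fill of the lumen by cells, wall refractive-index statistics,
    geodesic distance-from-break profiles with moving mean/SD, and group-level
    t/F statistics with per-animal aggregation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
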