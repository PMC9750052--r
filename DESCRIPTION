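Package: pulmflow
Title: Geometric Multiscale Simulation of Pulmonary Arterial Hemodynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-loop lumped-parameter (0D) model of the human circulation
    with time-varying chamber elastances and smoothed-diode cardiac valves,
    coupled to a pluggable distributed ("3D") model of the pulmonary arteries
    through partitioned 3D-0D algorithms (splitting-explicit, splitting-implicit
    and one-way). Ships an RLC pulmonary-artery surrogate for desk-scale
    coupling studies, an optional stabilized equal-order finite-element solver
    for incompressible flow in an idealized rigid tube (SUPG/PSPG, backflow
    stabilization, defective boundary conditions, wall-shear-stress
    post-processing), Richardson mesh-convergence extrapolation, per-beat
    hemodynamic metrics, pressure-volume loops and a pulmonary-arterial
    hypertension scenario obtained by quintupling the distal resistance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
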