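Package: aneuflow
Title: Lattice Boltzmann and Navier-Stokes Simulation of Aneurysm Hemodynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Steady laminar blood-flow simulation in synthetic aneurysm-bearing
    vessels, with and without an endoluminal stent. Implements a D2Q9/D3Q19
    single-relaxation-time (BGK) lattice Boltzmann solver with half-way
    bounce-back walls, a parabolic velocity inlet and a zero-gradient outlet,
    alongside a staggered-grid incompressible Navier-Stokes projection solver
    used as an independent reference. Vessel, sac and stent geometries are
    generated from level-set descriptions; post-processing provides cutline
    velocity profiles, sac-averaged and neck-peak velocities, vorticity and
    cross-solver comparison metrics, together with scenario presets, a config
    file format and CSV/JSON/VTK export.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
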