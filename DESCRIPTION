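Package: ionwater
Title: Data-Driven Polarizable Halide-Ion/Water Potentials, Fitting and
    Cluster Optimization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for building and benchmarking bottom-up polarizable
    halide-anion/water interaction potentials of the Thole-type (TTM)
    family: Born-Mayer repulsion, Tang-Toennies damped dispersion,
    smeared-charge permanent electrostatics and self-consistent
    many-body induced-dipole polarization.  Includes spherical-grid
    dimer training-set construction with energy-based weighting, a
    two-stage (SVD + simplex) parameterization engine with an
    active-learning reweighting loop, a self-adaptive
    evolutionary-programming optimizer for locating minimum-energy
    cluster structures, and an interaction-energy benchmark protocol
    comparing model and ingested quantum-chemistry energies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
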