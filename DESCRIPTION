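Package: minibeam
Title: Magnetically Focussed Proton Minibeams: Beamline Optics, Quadrupole
    Optimisation and Water-Phantom Dose Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Desk-scale simulation of proton minibeam generation by magnetic
    focussing in a clinical pencil-beam-scanning nozzle. Provides an
    emittance-parametrised bi-Gaussian beam source, analytic sigma-matrix
    (envelope) and Monte Carlo transport through configurable beamline
    geometries with quadrupole focussing, multiple Coulomb scattering
    (Highland/Fermi-Eyges) and thin material slabs, an exhaustive
    quadrupole-field grid search minimising the combined beam-size statistic
    Omega = hFWHM^2 + vFWHM^2, a source-parametrisation feasibility benchmark
    with measured-beam-size calibration, and an analytic pencil-beam dose
    engine for minibeam grids in a water phantom with peak-to-valley dose
    ratio (PVDR), depth-dose and beam-width analysis.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    pracma,
    minpack.lm,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
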