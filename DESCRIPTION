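Package: hbridge
Title: Intramolecular Hydrogen-Bridge Proton Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for the dynamics of short intramolecular
    O-H...O hydrogen bridges. Provides a surrogate two-bridge double-well
    Langevin simulator that emulates the statistical structure of ab initio
    molecular-dynamics trajectories, XYZ trajectory input/output, bridge
    distance time series, Voronoi proton-possession statistics,
    proton-transfer event detection, two-dimensional donor-proton
    correlation histograms, velocity-autocorrelation power spectra,
    discrete proton-potential scan analysis with barrier uncertainty, and
    an a posteriori nuclear-quantum-effects workflow (arc-based proton
    paths, polynomial potential fits, a sine-DVR grid solver for the 1D
    vibrational Schroedinger equation, and thermal expectation values of
    the donor-proton distance).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
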