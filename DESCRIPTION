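Package: dressedEPR
Title: Dressed-Spin Pulsed Dipolar EPR Simulation and Distance Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for nanometre distance measurement
    between electron spins by spin-locked (dressed-spin) pulsed electron
    paramagnetic resonance with phase-modulated pulses. Provides product-basis
    spin operators and dipolar Hamiltonians for two coupled spin-1/2 electrons,
    first-order average-Hamiltonian results in the nutating frame (offset and
    hyperfine decoupling, -1/2 dipolar scaling), exact density-matrix
    propagation of the phase-modulated dressed-echo sequence, a fast
    Monte-Carlo phase-inversion simulator for powder ensembles with finite
    Rabi-frequency artifacts, and a processing pipeline that turns dipolar
    time traces into stretched-exponential relaxation constants, Pake-type
    dipolar spectra and distances.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
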