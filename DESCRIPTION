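Package: fflux
Title: Fluorescence Fluctuation Spectroscopy Simulation and Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing fluorescence fluctuation
    spectroscopy experiments on membrane receptors. Provides a Brownian-dynamics
    forward simulator that generates binned photon-count traces from freely
    diffusing solution species and membrane-confined species observed through a
    3D-Gaussian confocal detection volume (including triplet/dark-state
    photophysics and Poisson photon statistics), a multi-tau autocorrelator,
    calibrated multi-component fluorescence correlation spectroscopy (FCS) model
    fitting with beam-waist calibration against dye diffusion standards and
    conversion of dwell times to diffusion coefficients and particle densities,
    photon counting histogram (PCH) molecular-brightness analysis with one- and
    two-component models and a first-order out-of-focus correction, Emax
    concentration-response fitting, and an experiment pipeline that reproduces
    condition-level summary tables from synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    minpack.lm,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
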