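Package: nmrmixsim
Title: Simulation of Realistic 1D 1H-NMR Spectra of Metabolite Mixtures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates realistic one-dimensional proton NMR spectra of
    complex metabolite mixtures such as human urine. Pure-compound standard
    spectra from a local NMR standard spectra database (Bruker-style
    processed data or plain-text) are preprocessed (regridding, exclusion
    regions, moving-median baseline correction, negative-artifact removal,
    kernel smoothing, unit-integral normalisation) and combined linearly,
    weighted by simulated metabolite concentrations and proton counts.
    Concentrations are drawn from truncated normal distributions, optionally
    with user-specified inter-metabolite correlations repaired to the
    nearest positive semidefinite correlation matrix. pH-driven peak
    positional shifts follow the Henderson-Hasselbalch relation between
    acid and base limit positions, and noise is added at a user-controlled
    signal-to-noise ratio then smoothed to mimic apodization. Includes a
    synthetic standards generator with Lorentzian multiplets so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    Matrix,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
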