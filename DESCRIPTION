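Package: vfret
Title: Vibrating-FRET Microfluidic Viscometry: Forward Simulation and Inverse Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulator and inverse estimator for an acoustofluidic
    viscometer based on vibrating Forster resonance energy transfer (VFRET).
    An acoustically entrained donor micro-particle oscillates relative to an
    acceptor layer, producing a periodic, viscosity-dependent FRET emission
    signal observed as noisy photon counts. The package implements the
    closed-form entrainment physics, the photon-budget and Gaussian noise
    model, period fold-averaging, sample filtering, Levenberg-Marquardt
    estimation of fluid viscosity and donor position, and a Monte Carlo
    harness for estimator-performance studies versus signal-to-noise ratio.
License: MIT
Encoding: UTF-8
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
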