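Package: driftcsf
Title: Contrast Sensitivity Predicted from Fixational Ocular Drift and
    Retinal Ganglion Cell Filters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the primate contrast sensitivity function (CSF) as the
    outcome of fixational ocular drift interacting with the spatiotemporal
    filters of magno- and parvocellular retinal ganglion cells. Provides a
    Brownian-motion generator for fixational drift, reconstruction of the
    space-time power spectrum of the retinal input to a drifting sinusoidal
    grating via complex demodulation, difference-of-Gaussians spatial kernels
    and linear-cascade temporal transfer functions, and a pipeline that
    combines them into predicted CSFs for static, flickered, and retinally
    stabilized viewing conditions, together with shape descriptors
    (band-pass/low-pass classification, peak location) and analytic
    Lorentzian oracles for the Brownian case.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
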