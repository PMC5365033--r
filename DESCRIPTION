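Package: mlfdwi
Title: Mittag-Leffler and Continuous-Time Random Walk Models for Diffusion MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parsimonious anomalous-diffusion models for diffusion-weighted MR
    signal decay. Provides a validated numerical evaluator for the one-parameter
    Mittag-Leffler function on the negative real axis, the two- and
    three-parameter Mittag-Leffler signal models alongside monoexponential and
    diffusional-kurtosis (DKI) references, the closed-form conversion between
    the time-fractional order and excess kurtosis, Rician noise correction,
    voxelwise Levenberg-Marquardt parameter mapping from 4-D NIfTI stacks, a
    one-dimensional continuous-time random-walk Monte Carlo simulator with
    Pareto waiting-time and jump-length laws, and a synthetic multi-b-value
    brain phantom generator for end-to-end validation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    RNifti,
    jsonlite,
    parallel,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
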