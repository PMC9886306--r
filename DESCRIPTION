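Package: angiocal
Title: Multilevel Calibration of a Hybrid Multiscale Model of Tumor Angiogenesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for calibrating a hybrid agent-based/continuum model of
    tumor-induced angiogenesis against multimodal measurements from a 3D
    vascularized microfluidic platform. Provides ODE models of VEGF
    production and consumption with daily media resets, Bayesian parameter
    estimation by naive grid quadrature and Metropolis-Hastings sampling,
    an agent-based model of tip/stalk-cell sprouting coupled to a
    reaction-diffusion VEGF field, a vessel-image pipeline (projection,
    thresholding, Zhang-Suen skeletonization, centerline distances), five
    sequential calibration scenarios with uncertainty propagation, and
    synthetic-data generators emulating hemocytometer counts, ELISA VEGF
    series and confocal image stacks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    EBImage,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
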