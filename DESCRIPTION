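Package: depotABP
Title: Energy-Depot Model of Active Brownian Particles Driven by Correlated Noise
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Stochastic simulator and analytic Fokker-Planck layer for the
    energy-depot model of active Brownian particles subject to cross-correlated
    multiplicative and additive Gaussian white noise. Provides Stratonovich-
    consistent stochastic Heun (second-order Runge-Kutta) integration of the
    full position-velocity-depot system, its adiabatically reduced velocity
    dynamics, and the equivalent single-noise Langevin equation; the effective
    velocity potential and stationary velocity distribution of the associated
    Fokker-Planck equation; and estimators for the transport observables
    (mean velocity, mean position, depot energy, energy conversion rate,
    effective diffusion coefficient) together with sweep orchestration that
    regenerates the model's figure experiments at configurable scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
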