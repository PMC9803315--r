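Package: tgfctrl
Title: Optimal Control of TGF-beta in Reaction-Diffusion Models of Lung Fibrosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Homogenized reaction-diffusion models of myofibroblast and
    fibroblast density on a two-dimensional tissue square, together with
    optimal-control synthesis for the TGF-beta forcing term: an
    unconstrained linear-quadratic regulator (algebraic and differential
    Riccati equations with an affine offset), a lower-bound-constrained
    controller obtained from Pontryagin's minimum principle with
    per-step KKT branching, and a coupled two-species controller with a
    four-case admissibility analysis. Includes explicit finite-difference
    discretization with no-flux boundaries, forward simulation of the
    uncontrolled kinetics, CSV/JSON run reporting, and a command-line
    driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
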