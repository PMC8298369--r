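Package: photofenton
Title: Kinetic and Radiation-Field Modelling of Fenton and Photo-Fenton
    Paracetamol Degradation in an Annular Photoreactor
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a reduced kinetic model for the Fenton and
    photo-Fenton degradation of paracetamol (PCT) under the steady-state
    radical approximation, a line-source spherical-emission (LSSE) radiation
    model giving the volume-averaged local volumetric rate of photon
    absorption (LVRPA) in an annular photoreactor, the well-stirred
    batch-recycle reactor mass balances, and multi-experiment nonlinear
    least-squares estimation of the kinetic constants.  A synthetic-data
    generator emulates the 3 x 3 x 2 factorial experimental design with
    species-specific sampling schedules and instrument-level Gaussian noise,
    so every stage of the pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
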