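Package: sterolkin
Title: Compartmental Kinetic Modelling of Intracellular Sterol Transport
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Kinetic modelling of sterol trafficking between the plasma
    membrane, recycling endosomes and late endosomes/lysosomes (with an
    intraluminal-vesicle sub-compartment) in human fibroblasts. Provides the
    linear compartment models as ODE systems, analytic steady-state amounts
    and fractions of the open system, a two-pathway efflux model with
    Weibull-delayed lysosomal exocytosis, global nonlinear regression of rate
    constants to multi-compartment fluorescence time courses, offset-Weibull
    fitting of efflux curves, AIC/BIC model selection, and a synthetic
    time-course generator for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils
Suggests:
    Matrix,
    jsonlite,
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
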