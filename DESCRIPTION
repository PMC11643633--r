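Package: durogel
Title: Mechanosensitive Active Gel Simulation of Amoeboid Durotaxis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates amoeboid cell migration on substrates with a stiffness
    gradient using a mechanosensitive active polar gel model: a phase-field
    actin droplet with a polarity field, non-muscle myosin II transport whose
    diffusivity depends on locally sensed substrate stiffness, and
    incompressible actomyosin flow solved in vorticity/stream-function form on
    a periodic grid. Includes trajectory directionality statistics for cell
    tracks (forward migration index, velocity, persistence, angular
    displacement), a persistent-random-walk synthetic track generator with
    tunable up-gradient drift, and a fast compiled Runge-Kutta core with a
    pure-R reference implementation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
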