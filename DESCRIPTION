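Package: oysterDEB
Title: Dynamic Energy Budget Models for Flat and Pacific Oysters
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Individual bioenergetics of the European flat oyster (Ostrea
    edulis) and the Pacific cupped oyster (Crassostrea gigas) through
    Dynamic Energy Budget (DEB) theory. Implements the 'asj' model with
    metabolic acceleration between settlement and the end of metamorphosis,
    a five-parameter Arrhenius temperature correction, Holling type-II
    feeding on chlorophyll-a, life-cycle event handling (brooding, larval
    release, spawning, ageing), an adaptive Runge-Kutta simulator with
    event localisation, a covariation-style parameter-estimation engine
    minimising a weighted mean-relative-error loss with the Nelder-Mead
    simplex, and a seeded synthetic-data generator so that estimation and
    validation are testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
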