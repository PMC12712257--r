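Package: bronchosim
Title: Endotracheal Tube Resistance and Ventilation Impairment Modelling
    During Bronchoscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the nonlinear pressure-flow resistance of endotracheal
    tubes with and without an inserted bronchoscope (Rohrer equation,
    effective-diameter scaling law) and couples it to a single-compartment
    respiratory-system simulator for volume-controlled, pressure-controlled,
    and automatic-tube-compensation ventilation. Reports intrinsic PEEP and
    tidal volume, provides least-squares fitting of Rohrer coefficients from
    bench pressure-flow sweeps and of power-law resistance scaling, and
    includes synthetic bench-data generators so every fitting and simulation
    path can be exercised without external recordings.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
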