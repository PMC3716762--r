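Package: stemheat
Title: Two-Dimensional Tree-Stem Heating and Fire-Injury Simulation
Version: 0.1.0
Authors@R:
    person("stemheat", "developers", email = "stemheat@example.org",
           role = c("aut", "cre"))
Description: Physically based two-dimensional (polar grid) simulation of heat
    transfer in tree stems exposed to fire. A Crank-Nicolson finite-volume
    solver integrates the cylindrical heat-conduction equation with
    moisture- and temperature-dependent wood and bark thermophysical
    properties, prescribed per-wedge fire heat-flux forcing with net
    black-body radiant exchange, Arrhenius desiccation and bark-charring
    energy sinks, and a rate-process tissue-viability model yielding
    necrotic depth around the stem circumference. Includes species-level
    water-loss-rate calibration against reference observations,
    circumferential-heterogeneity and height virtual experiments, and
    command-line entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
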