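Package: exersist
Title: Compartmental Dynamics of Social Influence on Exercise Persistence
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses a three-compartment ordinary
    differential equation model of physical-activity behaviour in a closed
    population, in which sedentary (S), moderately active (E1) and extremely
    active (E2) individuals exchange members through mass-action social
    contact and spontaneous transitions. Provides the right-hand side of the
    system, adaptive-step integration of scenarios with plateau and
    extinction detection, the basic reproduction number R0 by a closed-form
    quadratic-root expression and independently by a numerical
    next-generation-matrix construction, the transmission-free and
    reduced-contact special cases with their persistence thresholds, and a
    one-at-a-time sensitivity protocol measuring the response of the
    long-run sedentary fraction to each rate constant. A command-line
    script exposes simulation, R0 reports, parameter sweeps and scenario
    presets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
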