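Package: h2ferm
Title: Kinetic Modeling of Dark-Fermentative Biohydrogen Batch Cultures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and parameter estimation for batch dark fermentation
    of glucose to hydrogen by the extreme thermophile Caldicellulosiruptor
    saccharolyticus. Couples Monod growth kinetics with Han-Levenspiel-type
    inhibition by dissolved hydrogen and by osmolarity, growth-associated
    (Luedeking-Piret) formation of acetate, lactate, hydrogen and carbon
    dioxide, liquid-to-gas mass transfer under nitrogen stripping, and
    carbonate speciation at controlled pH. Provides a stiff ODE simulator
    with mass-balance audits, a two-stage nonlinear least-squares parameter
    estimation pipeline with linearized confidence intervals, a synthetic
    batch-experiment generator for recovery studies, and operating-condition
    diagnostics (dissolved-hydrogen oversaturation, steady-state dissolved
    hydrogen, critical mass-transfer coefficients and response surfaces).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    MASS,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
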