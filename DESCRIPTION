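Package: thymodyn
Title: Delayed Compartmental Modeling of Mouse Thymocyte Development
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modeling the development and involution of the mouse
    thymus as a five-compartment delay-differential system (double-negative,
    double-positive, CD4 and CD8 single-positive thymocytes, plus an apoptotic
    sink) with exponentially decreasing proliferation rates and an optional
    density-dependent growth brake. Includes a method-of-steps integrator with
    a prenatal/postnatal parameter switch at birth, developmental milestone
    extraction (population emergence times, composition crossings), model
    calibration by differential evolution hybridized with Nelder-Mead under a
    mean-squared-error objective, bootstrap confidence intervals, in-silico
    progenitor-ablation scenarios, and a synthetic-data generator emulating
    staged prenatal/postnatal thymocyte census designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
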