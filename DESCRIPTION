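Package: verikit
Title: Validation, Repair, and Cross-Engine Verification of SBML/SED-ML
    Simulation Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for curating and verifying mechanistic ODE models
    exchanged as COMBINE/OMEX archives. Reads, writes, and structurally
    validates OMEX archives and their manifests; parses and semantically
    validates the time-course subset of SED-ML; applies a deterministic,
    replayable catalogue of repairs to defective SED-ML and SBML files;
    generates template time-course experiments for models lacking curated
    ones; executes experiments on interchangeable simulation engines,
    including a built-in reference ODE engine with initial-value-scaled
    absolute-tolerance vectors; and verifies that independent engines
    replicate each other's results under a relative-plus-range-scaled
    tolerance criterion. Ships a synthetic-fixture generator (mass-action
    chains with closed-form solutions, multi-scale initial values, and
    deliberately defective archives) so the whole pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    xml2,
    deSolve,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    Matrix
Config/testthat/edition: 3
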