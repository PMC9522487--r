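Package: leukegame
Title: Evolutionary Game and Predator-Prey Dynamics of Leukemia
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Dynamical models of the interaction between healthy leukocytes
    (leu), cancerous leukocytes (c.leu) and transplanted hematopoietic stem
    cells (HSC): Hawk-Dove replicator dynamics on the frequency simplex, a
    Leslie-Gower predator-prey system with closed-form coexistence
    equilibrium and trace-determinant stability analysis, and a
    two-coalition bimatrix replicator game for post-transplant dynamics.
    Includes a shared 2x2 linear-stability toolkit, ODE/map simulation
    machinery with basin-of-attraction sampling, clinically parameterised
    scenario presets with a seeded random scenario generator, and CSV/JSON
    report writers plus a thin command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
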