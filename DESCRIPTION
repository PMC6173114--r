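Package: epilattice
Title: Logical Modelling of Epithelial Dynamics on Hexagonal Cell Grids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates monolayer epithelia as cellular automata over 2D
    hexagonal grids in which every cell runs a qualitative (Boolean or
    multi-valued) logical regulatory model. Cells communicate through logical
    integration rules that set the input components of a cell from the states
    of its neighbours (counting signals over distance bands), or through
    constant positional inputs such as morphogen gradients. Tissue dynamics
    evolve under synchronous or alpha-asynchronous updating with optional
    priority classes, component perturbations restricted to grid regions, and
    epithelium clones for multi-phase simulations. Cellular models are
    exchanged as SBML Level 3 'qual' documents; projects are stored in a
    plain-text YAML dialect and trajectories exported as CSV.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    grDevices,
    graphics,
    png,
    stats,
    xml2,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
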