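Package: chemoscale
Title: Multiscale Models of Bacterial Chemotaxis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates bacterial chemotaxis signal transduction and population
    pattern formation across scales: equilibrium activity of chemoreceptor
    trimer-of-dimer clusters under a Monod-Wyman-Changeux two-state free-energy
    model, the two-variable linear excitation-adaptation model of intracellular
    signalling, a stochastic velocity-jump run-and-tumble agent simulator
    coupled to reaction-diffusion attractant and nutrient fields, and the
    derived Patlak-Keller-Segel continuum equation whose transport coefficients
    are computed from the microscopic cell parameters.  Includes Hill-function
    fitting for cooperativity analysis of dose-response curves, canned
    scenarios for canonical single-cell and population experiments, and
    cross-scale consistency checks between the agent-based and continuum
    descriptions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
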