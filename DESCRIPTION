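Package: phoscycle
Title: Kinetic Modelling of cMyBP-C Multisite Phosphorylation by Kinases and Phosphatases
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An integrated kinetic model of the multisite phosphorylation of the
    cardiac myosin-binding protein-C (cMyBP-C) m-motif by the kinases PKA, RSK2
    and PKC-epsilon and its dephosphorylation by the phosphatases PP1 and PP2A.
    Implements the eight/nine-state reaction network with competitive
    Michaelis-Menten rate laws and three mechanistic extensions (phenomenological
    activation, allosteric activation, structural transition), plus a total
    quasi-steady-state rate mode for low substrate regimes. Provides fixed-step
    and adaptive ODE integration, steady-state solvers, a synthetic-data
    generator with known ground truth, ensemble parameter calibration by a
    genetic algorithm refined with Hooke-Jeeves pattern search, AIC-based model
    selection, steady-state dose-response and Hill analyses, and inference of
    enzyme concentrations from steady-state phospho-distributions including
    maximally achievable fraction (MAF) optimisation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    pracma,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
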