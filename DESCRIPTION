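Package: ligandmsm
Title: Markov State Models for Ligand-Binding Kinetics and Thermodynamics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs ligand-binding thermodynamics and kinetics from
    ensembles of short trajectories using Markov state models. Provides
    contact-map featurization of receptor-ligand trajectories, time-lagged
    independent component analysis (TICA), k-centers discretization with
    ion-coordination cluster splitting, reversible maximum-likelihood
    transition-matrix estimation with implied-timescale lag selection, PCCA
    macrostate lumping, mean first passage times and committors, association
    and dissociation rate constants (kon, koff) with standard binding free
    energies, and bootstrap error estimation. Ships synthetic trajectory
    generators (continuous-time Markov jump processes embedded in feature
    space, and Brownian ligand-binding simulations) with analytic ground
    truth so every pipeline stage is verifiable without molecular-dynamics
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
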