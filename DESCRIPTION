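Package: mpsn
Title: Multi-Pathway Spatial Networks and Multi-Scale Epidemic Spread
Version: 0.1.0
Authors@R:
    person("MPSN", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Generator for multi-pathway spatial networks (MPSN): lattice
    vertices carrying three superposed, pathway-labeled edge layers modelling
    self-mediated dispersal (short range), within-locality spread, and
    long-distance human-mediated jumps between localities. Provides spectral
    (spectral radius, full spectra) and metric (diameter) structural analysis
    with checkers for the model's spectral-radius sandwich bounds and
    diameter scaling; a discrete-time SEI diffusion simulator with
    pathway-specific infection probabilities, ensembles, and pathway
    unraveling experiments; a full-factorial sweep designer with a built-in
    CART/random-forest importance engine for simulation metamodeling; and
    reading, writing, and synthesis of temporal directed weighted
    commodity-flow networks with monthly weighted/unweighted spectral
    profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    methods,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
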