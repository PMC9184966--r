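Package: linfra
Title: Linear Framework Graphs: Matrix-Tree Steady States, Thermodynamics
    and Sharpness of Biomolecular Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models biomolecular systems as finite, simple, directed graphs
    with positive edge labels (rates), the so-called linear framework. The
    graph Laplacian generates a linear dynamics on vertex concentrations or
    state probabilities; steady states are computed exactly via the
    Matrix-Tree theorem as positive sums over rooted spanning trees, either
    symbolically over the rate parameters or numerically. On top of this
    core the package provides a stochastic-thermodynamics layer (path
    products, the Wegscheider cycle condition, detailed balance,
    equilibrium Boltzmann-type steady states, per-edge entropy changes),
    partition-based coarse graining that preserves steady-state
    aggregates, input-output response functions with position-steepness
    sharpness analysis against Hill-function references, and the rational
    reduction of enzyme-catalysed modification cycles to enzyme
    conservation equations with aggregated Michaelis-Menten-type
    parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
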