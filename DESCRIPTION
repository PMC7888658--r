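Package: nevosim
Title: Agent-Based Simulation of Melanocytic Nevi on a Geometric Model
    of the Dermo-Epidermal Junction
Version: 0.1.0
Authors@R:
    person("Nevosim", "Developers", email = "nevosim@example.org",
           role = c("aut", "cre"))
Description: Simulates the growth of melanocytic nevi as off-lattice
    melanocyte agents that proliferate, differentiate into nest-forming
    strains and migrate along (or detach from) the dermo-epidermal
    junction.  The basement membrane is modeled as a composite
    two-dimensional manifold built from B-spline surfaces of revolution
    for dermal papillae; cell motion on the membrane is integrated as
    geodesics of the induced metric.  Includes procedural membrane
    synthesis from papilla shape statistics, dermatoscopy- and
    histology-style rendering of simulated populations, and growth
    quantification (enclosing-disk and quantile-disk lesion area, growth
    slopes, nest statistics) together with deterministic aggregate
    models that serve as independent oracles for the stochastic engine.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    splines,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
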