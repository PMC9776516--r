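Package: ionatmos
Title: Ion Atmosphere Maps and Statistics Around Charged Macromolecules
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to characterise the ionic environment around a fixed,
    irregularly charged macromolecule in electrolyte solution.  Builds
    three-dimensional ion concentration maps either from particle
    trajectories (triangular-kernel density estimation on a regular grid)
    or from grid solutions of the linear and nonlinear Poisson-Boltzmann
    equation followed by Boltzmann inversion of the potential.  Computes
    ion excess, total-charge and ionic-strength profiles as functions of
    the distance to the closest macromolecular atom, molality-based radial
    distribution functions, concentration dispersion summaries and
    iso-concentration masks, and implements the neutrality-plus-ionic-
    strength ion-addition protocol used to salt simulation boxes.  A
    Metropolis Monte Carlo sampler of screened-Coulomb electrolytes
    generates synthetic systems with known statistics for validation.
    Reads and writes PQR structures, OpenDX scalar grids (APBS dialect)
    and a minimal extended-XYZ trajectory dialect.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    graphics,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
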