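Package: ireplan
Title: Treatment-Planning Simulation for Irreversible Electroporation of
    Liver Tumors
Version: 0.1.0
Authors@R:
    person("ireplan", "developers", email = "ireplan@example.org",
           role = c("aut", "cre"))
Description: Voxel-based simulator for planning percutaneous irreversible
    electroporation (IRE) of liver tumors near major blood vessels. Solves
    the stationary electric problem with field-dependent tissue conductivity
    for each energized needle-electrode pair, combines per-pair fields into
    coverage curves and lesion volumes, runs a duty-cycle Pennes bioheat
    model over the full pulse protocol, and accumulates Arrhenius thermal
    damage. Ships a synthetic liver/tumor/vessel case generator and
    protocol/material tables with literature defaults.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
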