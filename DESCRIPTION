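Package: crossnet
Title: Brownian Dynamics of Short Rigid Actin Filaments with Elastic Crosslinkers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the self-organization of short (< 220 nm) rigid actin
    filaments connected by elastic crosslinking proteins (e.g. fimbrin) under
    conditions relevant to clathrin-mediated endocytosis. Filaments are rigid
    rods with helical subunit geometry moved by overdamped anisotropic Brownian
    dynamics; crosslinkers are extensional plus torsional springs with
    stochastic formation and energy-dependent slip-bond breakage. Provides
    structural observables (Q-tensor nematic order, crosslink-graph clusters,
    bundle/meshwork phase classification), crosslinker strain and elastic
    energy statistics with Boltzmann references, and closed-form companion
    models: torque generation by ordered crosslinker detachment, the
    crosslinker-number master equation and effective binding energy, filament
    rigidity checks, and a membrane-work estimate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
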