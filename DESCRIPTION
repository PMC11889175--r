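Package: rnfpump
Title: Redox-Coupled Sodium Pumping Models for the Rnf Complex
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Bioenergetic accounting, electron-transfer and barrier-crossing
    kinetics, and a master-equation simulator of the ten-step redox-driven
    sodium pumping cycle of the membrane-bound ferredoxin:NAD+ oxidoreductase
    (Rnf) complex, with membrane-potential (sodium-motive-force) coupling.
    Also provides structure-level cofactor network analysis (iron-sulfur
    cluster and flavin detection, ligating-cysteine geometry, edge-to-edge
    distances, iron-content accounting, variant effects), trajectory
    analytics for alternating-access gating, ion-pair states, sodium axial
    densities, 2D potentials of mean force and ion-pathway continuity, and
    seeded synthetic-data generators so the full pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    deSolve,
    graphics,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
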