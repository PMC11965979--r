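Package: pathmetad
Title: Path Collective Variables, Well-Tempered Metadynamics and
    Trajectory Analysis for Receptor Activation Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for mapping large-scale conformational transitions
    such as G protein-coupled receptor activation with path collective
    variables (progress s and distance z from a reference path, in either
    a coordinate-RMSD or a contact-map metric), well-tempered
    metadynamics with free-energy reconstruction and reweighting, steered
    and wall restraints over a built-in Langevin sampler, and the
    companion trajectory analyses: dynamical cross-correlation of
    C-alpha fluctuations, region RMSD, ionic-lock distance probes with
    occupancies, and protein structure networks (interaction strengths,
    hubs, cross-frame metapaths).  A synthetic fixtures module provides
    two-state bead-chain receptors with analytically known free-energy
    surfaces so the whole stack is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    jsonlite,
    MASS,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
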