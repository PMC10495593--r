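Package: wormblob
Title: Agent-Based Simulation of Worm-Blob Collective Locomotion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-dimensional agent-based model of tubificine worm blobs:
    deformable, self-propelled cross-shaped agents with contact-dependent
    elongation, nematic alignment, a self-released diffusing chemorepellent
    field, and peg/wall interactions. Builds the standard arenas (square box,
    open dish, oval, dumbbell, dumbbell with pegs), advances the coupled
    agent-field system with a stiffness-aware two-stage Runge-Kutta scheme,
    and post-processes trajectories into blob clusters, blob-centre tracks,
    one-way-trip counts and rank-sum comparisons between arena conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
NeedsCompilation: yes
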