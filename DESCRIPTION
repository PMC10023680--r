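Package: funneldock
Title: Decision Analytics for Nanobody Dock-and-Design Pipelines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processing and decision stages for computational nanobody
    paratope design against a target epitope: curation of candidate nanobody
    chains, steric triage of docked initial poses by a heavy-atom clashscore,
    selection of poses with funnel-shaped binding-energy landscapes, cycled
    multi-criteria selection of first-round designs, affinity-maturation
    candidate pooling with sequence-space diversification (PCA of residue
    descriptors plus density clustering), and CDR-loop flexibility analysis of
    molecular-dynamics trajectories. Docking, design and simulation engines
    are upstream; their pose, score-table and trajectory outputs are the
    inputs here, and seed-deterministic synthetic generators stand in for
    them during testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    seqinr
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    bio3d
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
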