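Package: compstab
Title: Stability and Feedback Structure of Interference Competition Networks
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for the local-stability analysis of interference competition
    networks parameterised from observed contests between sessile organisms
    (e.g. overgrowth competition among bryozoan colonies). Translates win/loss/draw
    species-contact matrices into energy-loss webs and per-capita Jacobian
    community matrices, computes the critical level of self-regulation s* by
    bisection and by the normalised-matrix eigenvalue shortcut, quantifies
    feedback-loop weights of all lengths by exact dynamic programming, measures
    pairwise and community asymmetry and contest-polarisation (win) indices,
    and runs null-model manipulations (full, weak and minimal randomisation,
    asymmetry restorations) and May-style random-matrix experiments that relate
    competitive hierarchy to network stability. Includes a synthetic-assemblage
    generator with controllable hierarchy steepness for testing and simulation
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
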