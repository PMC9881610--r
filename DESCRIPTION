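Package: gfedock
Title: Grid Free-Energy Docking and Consensus Scoring for hERG Blockade
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte-Carlo docking of small molecules in precomputed grid
    free-energy (FragMap) fields, with ligand grid free energy (LGFE)
    scoring, per-atom and per-moiety free-energy decomposition,
    Henderson-Hasselbalch ionization-state weighting, Markov-chain
    Monte-Carlo simulated-annealing reweighting of FragMap contributions
    against experimental affinities, a physicochemical multiple linear
    regression model, consensus scoring, and rank-ordering metrics
    (predictive index, percent correct) for hERG blockade prediction.
    Includes a synthetic-fixture generator (Gaussian-well maps,
    procedural ligands, affinity tables with known ground truth) so the
    full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
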