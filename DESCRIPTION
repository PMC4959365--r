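Package: commap
Title: Communication Mapping of Protein Dynamical Architecture from
    Conformational Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dissects the dynamical architecture of a protein from a
    conformational ensemble (e.g. molecular dynamics trajectories).
    Extracts five residue-based dynamic descriptors (local dynamical
    correlations from principal component modes, inter-residue minimum
    distances, communication propensities, non-covalent interaction
    strengths and secondary-structure persistences), auto-tunes the four
    analysis thresholds, grows independent cliques and enumerates
    communication pathways, assembles a Protein Communication Network
    (PCN), and reports communication blocks, block mappings between two
    protein states and communicating segment pairs with communication
    strengths.  Includes synthetic-ensemble generators for testing,
    a trajectory convergence diagnostic and PyMOL script emitters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    ncdf4,
    optparse,
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
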