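Package: abrescue
Title: Structure-Guided Antibody Rescue: Interface Mutation Scanning,
    Focused Library Design, and Panning Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for computationally guided rescue of antibody binding
    lost to antigen resistance mutations. Reads antibody-antigen complex
    structures from PDB files, evaluates binding energies with a
    self-contained heavy-atom pairwise force field (Lennard-Jones,
    distance-dependent-dielectric Coulomb on formal charges, distance-window
    hydrogen bonds, buried-surface solvation), performs rotamer-based point
    mutation and local side-chain repacking, generates structural ensembles,
    clusters them by interface fingerprint, and nominates hotspot positions
    whose substitutions are predicted to restore binding in every cluster.
    Downstream modules translate hotspots into degenerate-codon (NNS)
    focused phage-display libraries with exact diversity and coverage
    mathematics, and simulate coselection panning campaigns (prepan
    depletion, affinity capture, wash attrition, amplification, dual-target
    screening). Deterministic synthetic fixtures with engineered steric
    clash and salt-bridge rescue ground truth are generated in-package.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
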