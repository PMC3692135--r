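Package: LigandEgress
Title: Geometric Simulation of Protein-Ligand Unbinding Pathways
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes geometrically feasible ligand unbinding (egress) paths
    from a protein-ligand complex using a Manhattan-like Rapidly-exploring
    Random Tree (ML-RRT) planner. The ligand is treated as an articulated
    rigid body (pose plus rotatable-bond torsions, the active variables) and
    protein side-chains as passively flexible (torsions recruited only when
    they block progress). Scaled van der Waals overlap between non-bonded
    atoms is the sole feasibility condition. Includes PDB input/output,
    distance-based bond perception, a per-residue flexibility file format,
    path discretization to a fixed per-frame ligand displacement, first-
    occurrence ligand-environment contact reports, and synthetic channel
    fixtures with known analytic clearances for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    bio3d,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
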