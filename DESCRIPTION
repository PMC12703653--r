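Package: protaconf
Title: Knowledge-Based PROTAC Conformer Generation and Ternary-Complex Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for modelling heterobifunctional degraders (PROTACs):
    periodic kernel-density estimation of dihedral-angle preferences and
    torsion-rule libraries; constraint-respecting, probability-ordered
    depth-first conformer enumeration with the warhead and E3-recruiting
    fragments frozen in their protein-bound geometries; rigid-body
    ternary-complex assembly from monomer protein-ligand complexes via
    maximum-common-subgraph ligand alignment and Kabsch superposition;
    geometric clash- and surface-scoring with unbound-baseline subtraction;
    plausibility filtering; Calpha-based protein-protein RMSD evaluation; and
    clustering-based ensemble reduction using inertia-tensor orientation
    features, k-means and a regularised compromise-score.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    bio3d,
    ChemmineR,
    Biostrings,
    cluster,
    methods,
    stats,
    tools,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
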