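Package: mdrin
Title: Dynamic Residue Interaction Networks from Molecular Dynamics Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of two labeled conformational ensembles of a multi-domain
    protein (for example oxidized versus reduced molecular dynamics
    trajectories): domain-level geometric features (inter-domain distances,
    angles, torsions), essential dynamics (Kabsch superposition, RMSD,
    displacement cross-correlation, principal component analysis, projected
    free-energy landscapes), single-feature discrimination of the two states
    (optimal linear threshold and radial-basis support vector machine), and
    dynamic residue interaction networks built from per-frame typed residue
    interaction networks via a maximum-interaction-lifetime statistic, with a
    differential log2 fold-change network export to GraphML and SIF. Includes
    a synthetic-trajectory generator with known ground truth (rigid hinge
    motions, scripted interaction schedules, mixture-distributed features) so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    MASS,
    e1071,
    igraph,
    data.table,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
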