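Package: torsionForest
Title: Classifying Kinase Variant Drug Resistance from Backbone Dihedral
    Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for classifying protein kinase variants as drug-resistant
    or drug-sensitive from the backbone phi/psi dihedral-angle content of
    their conformational ensembles. Provides a synthetic ensemble generator
    with von Mises per-angle distributions, multi-model PDB and angle-matrix
    input/output, backbone torsion extraction, iterative Gini decision-tree
    feature selection, leave-one-variant-out random-forest classification
    with frame-to-variant vote aggregation, exact interventional Shapley
    attribution, circular statistics of class-averaged dihedral differences,
    and convergence diagnostics (Kabsch RMSD plateau detection, Ramachandran
    window comparison, windowed selection stability).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    randomForest,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
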