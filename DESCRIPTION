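Package: reorglam
Title: Conformer-Robust Prediction of Molecular Reorganization Energy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for predicting the internal reorganization energy (lambda)
    of small organic molecules from low-cost distance-geometry conformers.
    Implements Nelsen four-point lambda arithmetic, featurization of 3D
    conformers into attributed graphs and internal coordinates (bond lengths,
    bend angles, torsions grouped per rotatable bond), three molecular encoder
    families that differ in their geometric symmetry class (bond-rotation
    invariant 3D, distance-sensitive 3D, and pure 2D), the dual IP/EA and
    direct-lambda prediction schemes, a molecule-level split and
    conformer-augmented training protocol with split-repeat ensembling, and a
    cross-conformer robustness diagnostic. A synthetic fixture generator
    produces QM9-like molecules with graph-determined labels so the full
    pipeline runs without any external dataset. Conformer embedding and SMILES
    handling are delegated to RDKit through a bundled Python bridge.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: Python (>= 3.8) with RDKit, available as 'python' on PATH
Config/testthat/edition: 3
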