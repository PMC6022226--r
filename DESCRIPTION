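Package: coumarinQSAR
Title: 2D-QSAR Modelling of Coumarin-6-Sulfonamide Anti-Proliferative
    Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A quantitative structure-activity relationship (QSAR) pipeline
    for a series of seventeen coumarin-6-sulfonamide derivatives assayed
    against HepG2, MCF-7 and Caco-2 cancer cell lines.  Computes topological
    (Kier-Hall connectivity, atomic-composition information content),
    electronic (Gasteiger PEOE partial charges, dipole components) and
    geometric (solvent-accessible surface area, Jurs charged-partial-
    surface-area, principal-axis shadow) molecular descriptors from SMILES
    input; selects descriptor subsets by genetic function approximation
    scored with Friedman's lack-of-fit; fits and cross-validates multiple
    linear regression models; and reproduces the published activity
    transforms, residuals, model statistics and assay arithmetic of the
    study the compound set comes from.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineOB,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: Open Babel (via ChemmineOB); python3 with RDKit on
    the PATH (deterministic conformer generation)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
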