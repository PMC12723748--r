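Package: ZipperQC
Title: Quality Assessment of Predicted Leucine-Zipper Dimer Structures
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to audit predicted coiled-coil (leucine-zipper) dimer
    models produced by protein structure predictors. Classifies each
    two-chain model as a valid parallel leucine zipper or a broken one
    (antiparallel packing, misoriented core leucines, minimal interchain
    contact, sub-heptad interface), computes interface confidence metrics
    from predictor output (ipTM, mean pLDDT, mean interchain PAE, and the
    PAE-gated ipSAE score), screens g-e' electrostatic complementarity
    across the registered interface, superposes models with iterative
    outlier rejection, and benchmarks metric discrimination against
    experimentally derived dimerization ranks via ROC/AUC. Includes a
    Crick-parameterized synthetic coiled-coil generator with matched
    synthetic confidence bundles so the whole pipeline runs without any
    external predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    graphics,
    utils,
    tools,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    readxl,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
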