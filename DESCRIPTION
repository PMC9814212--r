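Package: logpnet
Title: Tautomer-Aware Prediction of the Octanol-Water Partition Coefficient
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for octanol-water partition coefficient (log P) modelling with
    graph convolutional networks and tautomer-based data augmentation. Provides a
    lightweight molecular graph engine (SMILES parsing, kekulization, aromaticity
    perception, canonicalization), rule-based tautomer enumeration, structure
    normalization and salt stripping, dataset curation (outlier and duplicate
    flagging), pH speciation and log D arithmetic, a pure-R graph convolutional
    regressor trained on augmented variant tables, and a seeded synthetic-molecule
    generator with an atom-additive log P oracle for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
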