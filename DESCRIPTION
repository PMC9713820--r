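Package: essmir
Title: Essential miRNA Prediction from Sequence and Secondary Structure
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "maintainer@example.org")
Description: Predicts essential microRNAs from precursor (pre-miRNA) and
    mature miRNA sequences. Combines a 38-dimensional statistic-and-structure
    feature of the hairpin (base contents, dinucleotide counts, cleavage-site
    class, minimum free energy and base-pair ensemble descriptors) with a
    learned sequence representation (k-mer embedding, bidirectional LSTM,
    multi-head scaled dot-product self-attention and a weight-attention
    fusion), classified by a multilayer perceptron trained with
    L2-regularised cross-entropy. Includes a built-in reference RNA folding
    engine (maximum base pairing and a McCaskill-style partition function),
    an adapter for the ViennaRNA RNAfold program, stratified k-fold
    cross-validation with AUC/accuracy/F1 reporting, and a seeded synthetic
    hairpin data generator for end-to-end testing.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
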