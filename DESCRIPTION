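Package: nabind
Title: Predicting Changes in Protein-Nucleic Acid Binding Affinity upon Mutation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structure-based prediction of the change in Gibbs free energy of
    protein-nucleic acid binding (ddG, kcal/mol) caused by single- and
    multiple-point missense mutations.  Features are extracted from the
    three-dimensional complex: graph-based structural signatures (cumulative
    pharmacophore pair-distance distributions around the mutation site),
    substitution-matrix scores, vibrational-entropy changes from an elastic
    network model, counts of thirteen geometric interaction types across the
    protein-nucleic acid interface, nucleic-acid-type indicators and the
    distance of the site to the interface.  An extremely-randomized-trees
    regressor trained under group-aware cross-validation maps these features
    to ddG.  Includes dataset utilities (mutation-string parsing, Kd
    conversion, hypothetical reverse-mutation augmentation, hot-spot and
    additivity labelling), a full evaluation suite, deterministic synthetic
    protein-nucleic acid fixtures, and a command-line interface with
    prediction and interface saturation-mutagenesis design modes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    ranger,
    pROC,
    optparse,
    stats,
    utils,
    tools,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    e1071
Config/testthat/edition: 3
RoxygenNote: 7.3.3
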