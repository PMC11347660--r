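Package: confsplit
Title: Conformational Splitting and Ensemble Evaluation for Protein Structure Corpora
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects alternative conformations of near-identical protein
    sequences in a structure corpus and builds conformational
    train/validation/test splits, so that structure-prediction models can be
    evaluated on conformations they have never seen. Provides a TM-score
    superposition engine with iterative fragment-seeded optimization, greedy
    sequence-identity and TM-threshold structural clustering, best-of-N
    evaluation of prediction ensembles with per-residue confidence,
    embedding-comparison statistics, an automated conformational-change
    classifier (hinge, rearrangement, fold switch), and a synthetic
    C-alpha structure generator with planted conformational changes for
    fully ground-truthed benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
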