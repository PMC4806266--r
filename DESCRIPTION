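Package: sulfire
Title: Tyrosine Sulfation Site Prediction with Fused Sequence Profiles and a Discrete Firefly Optimizer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts protein tyrosine sulfation residues from primary sequence
    and per-residue profile files. Nine-residue peptide windows centred on each
    tyrosine are encoded into a 472-dimensional fused descriptor built from
    PSI-BLAST position-specific scoring matrices, PSIPRED secondary-structure
    predictions, DISOPRED native-disorder probabilities and six physicochemical
    residue scales. Features are ranked by symmetric Kullback-Leibler divergence
    between class-conditional distributions, pre-selected by incremental feature
    selection under a cross-validated RBF-kernel support vector machine, and
    refined by a discrete firefly algorithm that co-optimizes the feature subset
    together with the SVM cost and kernel width. Includes a seeded synthetic-data
    generator that writes FASTA, PSSM, ss2 and disorder files with planted
    class-conditional signal so the whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    e1071,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
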