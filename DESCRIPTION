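Package: mpff
Title: Molecular-Protein Feature Fusion for Inhibitor Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Binary activity prediction and virtual screening of
    target-specific inhibitors by fusing graph-based compound
    representations with protein sequence representations. Provides an
    edge-conditioned message-passing encoder over molecular graphs, a
    residue-level protein encoder (one-hot or precomputed protein
    language-model embeddings), a cross-coupled feature-fusion module
    with a row-stochastic residue-by-atom association matrix, and a
    feedforward prediction head, together with AdamW training with
    early stopping, Gaussian-process Bayesian hyperparameter search,
    IC50-threshold dataset construction, Bemis-Murcko scaffold
    splitting, physicochemical library filtering, classification
    metrics and library screening. Cheminformatics (SMILES parsing,
    canonicalization, descriptors, scaffolds, graph featurization) is
    delegated to a bundled RDKit helper executed through the system
    Python interpreter.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
SystemRequirements: Python (>= 3.8) with the rdkit package importable
    from the interpreter found as 'python' on the PATH.
Imports:
    jsonlite,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
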