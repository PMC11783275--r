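Package: stabemb
Title: Protein Stability Change Prediction from Language-Model Embedding
    Differences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts the change in protein folding free energy (ddG, in
    kcal/mol) caused by single- and multi-point amino-acid substitutions.
    A variation is encoded as the element-wise difference between the
    per-residue embedding matrices of the wild-type and variant sequences;
    the difference matrix is regressed onto ddG by a compact network made
    of a 1D convolution, one transformer encoder layer (multi-head
    self-attention plus a position-wise feed-forward network, residual
    connections only), global average/max pooling and a linear output.
    The package implements the full training protocol (thermodynamic
    reversibility augmentation, Adam optimisation of the mean squared
    error with early stopping), a homology-aware k-fold cross-validation
    split that confines similar proteins to the same fold, and the
    standard evaluation statistics (PCC, RMSE, MAE, the direct/reverse
    correlation and the antisymmetry bias). A deterministic contextual
    mock embedder and seeded synthetic-task generators allow every stage
    to be exercised without external model weights or datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
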