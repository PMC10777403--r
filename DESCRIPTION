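Package: dmpnn
Title: Directed Message Passing Neural Networks for Molecular and
    Reaction Property Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains directed message passing neural networks (D-MPNN) on
    molecules and atom-mapped reactions written as SMILES. Molecules are
    featurized into directed multigraphs with one-hot atom and bond feature
    blocks; reactions are condensed into a single pseudomolecule (condensed
    graph of reaction). Supports regression, binary and multiclass
    classification, whole-spectrum targets with exclusion regions, and
    constrained atom- and bond-level targets; a menu of training losses
    (bounded MSE, mean-variance and evidential negative log-likelihood,
    Matthews-correlation and Dirichlet classification losses, spectral
    information divergence, Wasserstein); uncertainty estimation by
    ensembling, Monte-Carlo dropout, mean-variance estimation and evidential
    heads, with z/t-scaling, CRUDE, Platt and isotonic calibration and the
    standard uncertainty evaluation metrics; transfer learning with layer
    freezing; latent-representation export; and a deterministic synthetic
    fixture generator so every feature is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ChemmineR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
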