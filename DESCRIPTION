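Package: mdapred
Title: miRNA-Disease Association Prediction with Sparse Autoencoders and
    Multi-Layer Perceptrons
Version: 0.1.0
Authors@R:
    person("mdapred", "maintainers", email = "mdapred@example.org",
           role = c("aut", "cre"))
Description: Predicts unknown miRNA-disease associations from a sparse
    binary association matrix. Disease semantic similarity is computed over
    a MeSH-style ontology DAG with the Wang decay-factor model, miRNA
    functional similarity by best-match aggregation over associated disease
    sets. A sparse autoencoder (KL-divergence sparsity penalty) learns
    latent features of the association matrix and its transpose; latent and
    similarity features are fused per pair and classified with a
    feed-forward neural network. Includes clustering-based negative
    sampling, cross-validation and ranking harnesses, a planted-structure
    synthetic data generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
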