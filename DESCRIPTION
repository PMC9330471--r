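Package: aedecode
Title: Decoding Gene-Gene Association Networks from Autoencoder Weights
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Trains single-hidden-layer autoencoders on gene-expression
    matrices, one model per clinical phenotype, and decodes the trained
    weight matrices into signed, directed gene-gene association networks.
    The association score between an input gene and an output gene is the
    sum over hidden nodes of the products of encoder and decoder weights,
    so that top-scoring gene pairs recover co-expression structure the
    model has learned. Includes reconstruction-error phenotype
    classification, hyperparameter grid scan with cross-validation,
    preranked gene-set enrichment on per-hidden-node weight rankings, a
    synthetic two-class cohort simulator with planted factor structure,
    and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    fgsea,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
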