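Package: reactembed
Title: Reaction-Enhanced Graph Learning for Molecular Representations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns low-dimensional molecule embeddings from chemical
    reactions by combining two graph views: message passing over molecular
    graphs (atoms and bonds) and attention-based propagation over a
    reaction-aware graph whose edges connect reactants to products of the
    same reaction.  A key/memory attention network models each reaction as
    a learned translation between the summed reactant and product
    embeddings, trained with a margin ranking loss plus a cross-view
    InfoNCE contrastive loss.  Includes a seeded synthetic reaction-corpus
    generator, product-prediction ranking (MRR, Hit at 1), reaction
    classification and property-prediction feature export, and
    relation-embedding diagnostics against bond- and ring-count changes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    Matrix,
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    nnet,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
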