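Package: druggability
Title: Protein Druggability Prediction from Sequence Embeddings and Gene Ontologies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts protein druggability (the propensity of a protein to be
    targeted by a therapeutic molecule) from pooled residue embeddings of a
    protein language model combined with binary Gene Ontology annotation
    vectors. Provides leak-free SVM-weight feature selection nested inside
    cross-validation, a small fully specified neural classifier, a thirteen
    metric evaluation battery (including MCC, Cohen's kappa, diagnostic odds
    ratio, discriminant power and Kullback-Leibler divergence), lift curves,
    random-label null checks, Jeffries-Matusita feature separability, and the
    contact-map and point-cloud structure representations used for
    sequence-versus-structure comparisons. A synthetic-data generator makes
    every stage testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    bio3d,
    e1071,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
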