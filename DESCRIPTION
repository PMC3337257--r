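Package: meshent
Title: Maximum-Entropy Annotation of Biomedical Literature with MeSH Terms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains one binary maximum-entropy (penalized logistic) classifier
    per Medical Subject Headings (MeSH) term from labeled title, abstract,
    journal and publication-year features, and applies the models jointly for
    multi-label annotation of literature records. Implements tree-based
    semantic distance on the MeSH hierarchy for negative-example selection,
    exact-matching and Bernoulli naive Bayes baselines, threshold tuning on a
    held-out validation split, and per-term k-fold cross-validated
    macro-averaged precision/recall/F evaluation. Includes a synthetic corpus
    and toy-ontology generator so the full pipeline is testable without any
    external corpus.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    e1071,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
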