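Package: varprior
Title: Phenotype-Driven Prioritization of Clinically Reportable Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ranks rare-disease variants by the probability that a clinical
    analyst would report them. Combines phenotype-driven gene scores over the
    Human Phenotype Ontology (binary-vector cosine similarity and random walk
    with restart), a six-criterion clinical variant filter, encoding of
    heterogeneous variant annotations into a numeric feature matrix with
    univariate feature screening, four imbalance-aware binary classifiers,
    and per-case rank evaluation stratified by ACMG pathogenicity class.
    Includes a seeded synthetic-cohort generator so the full pipeline runs
    end to end without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    data.table,
    jsonlite,
    yaml,
    ranger,
    glmnet,
    rpart,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    igraph,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
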