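Package: assaycontext
Title: Assay-Context Descriptors, Topic Clustering, and Assay-Aware
    Proteochemometric Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Turns free-text biological assay descriptions and categorical
    assay metadata from ChEMBL-style exports into machine-usable descriptors
    (metadata one-hot fingerprints, bag-of-words fingerprints, dense text
    embeddings), groups similar assays into interpretable topics with
    class-based TF-IDF topic words and outlier reassignment, scores cluster
    assignments against categorical labels (normalized purity, adjusted
    mutual information, homogeneity/completeness/V-measure, Fowlkes-Mallows),
    quantifies how much of the replicate variance between repeated
    protein-compound measurements the assay groupings explain, and trains
    assay-aware proteochemometric gradient-boosting regression models that
    consume compound fingerprints, z-scale protein descriptors, and assay
    context jointly. Includes a synthetic-data generator with known archetype
    structure so every stage can be exercised and validated offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    igraph,
    xgboost,
    ChemmineR,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
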