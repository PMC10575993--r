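Package: synviab
Title: Synthetic Viability Gene-Pair Discovery and Immunotherapy Risk Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery and downstream analytics for synthetic viability
    (synthetic rescue) gene pairs in cancer. Computes fourteen pair-level
    features over protein-protein interaction, annotation and multi-omics
    data, trains a random-forest ensemble classifier for synthetic-viable
    pairs, filters candidates with a CRISPR dependency-screen regression
    (lineage-adjusted linear model with Benjamini-Hochberg correction),
    scores tumor samples by co-occurring pair alterations (SV-score),
    evaluates survival associations (Kaplan-Meier, log-rank, Cox), applies a
    six-pair risk signature for immune-checkpoint-inhibitor resistance in
    melanoma, and profiles the immune landscape via single-sample gene-set
    enrichment. Includes a synthetic-data generator that plants detectable
    rescue interactions so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    randomForest,
    stats,
    survival,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
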