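Package: surrosig
Title: Surrogate-Cohort Transfer Learning for miRNA Tumor Signatures in Rare Cancers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Biomarker discovery for rare tumors by transfer learning from a
    large surrogate cohort. Selects a surrogate tumor entity by Spearman
    correlation of mean miRNA profiles, stratifies it by principal component
    analysis, pre-filters concordantly deregulated miRNAs across cohorts,
    trains a balanced binomial elastic-net classifier with cross-validated
    penalty selection (lambda-min plus one standard error), evaluates it on
    independent tissue, cell and exosome datasets, and prunes the resulting
    signature to minimal panels by direction-concordance, read-share abundance
    and qPCR (delta-Cq, geNORM reference stability, Wilcoxon) confirmation.
    Includes a seeded negative-binomial cohort simulator so the whole workflow
    is testable without access to restricted patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet,
    optparse
Config/testthat/edition: 3
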