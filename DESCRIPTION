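Package: ceRNAscreen
Title: Competing Endogenous RNA Network Discovery and Prognostic Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end screening pipeline for circRNA-miRNA-mRNA competing
    endogenous RNA (ceRNA) regulation in tumor transcriptomics. Implements
    tumor-versus-normal differential expression with fold-change and p-value
    thresholds, Fisher exact overlap testing between differential-expression
    lists from independent cohorts, sign-constrained assembly of
    circRNA-miRNA-mRNA triplet networks from miRNA interaction tables,
    hypergeometric over-representation analysis against GMT gene-set
    collections, median-split Kaplan-Meier log-rank screening of network genes
    against overall survival, and Spearman correlation of gene expression with
    drug IC50 across cell lines under Benjamini-Hochberg false discovery rate
    control. A seeded synthetic-data generator plants known differential
    expression, ceRNA triplets, prognostic genes and drug-gene associations so
    that every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
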