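Package: stemscreen
Title: Stemness and Chemoresistance Target Prioritisation and Drug
    Repurposing from qPCR Array Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of TaqMan-style low-density qPCR array
    experiments comparing cancer stem-like cell models (3D spheroids,
    CD133-sorted populations) with bulk 2D cultures. Provides global-mean
    Ct normalisation, the comparative Ct method, expression tiering,
    empirical-Bayes moderated differential expression with
    Benjamini-Hochberg Q values, detection-set (Venn) analysis,
    self-renewal assay metrics, prioritisation of stemness and
    chemoresistance target genes, and a drug-repurposing stage that scores
    drug-gene interactions, aggregates clinical-trial registry extracts
    and builds a candidate report. A synthetic-data module fabricates
    every input format so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
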