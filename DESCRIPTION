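Package: icistrat
Title: Ex Vivo Anti-PD1 Response Stratification for Tumor Histocultures
Version: 0.1.0
Authors@R:
    person("icistrat", "maintainers", email = "devnull@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multimodal ex vivo immune-checkpoint-inhibitor
    response profiling of tumor histocultures. Provides T0-normalization and
    treated-vs-control fold-change computation for cytokine, histopathology and
    viability readouts; rule-based responder stratification (SC1, SC2a-d) on a
    seeded t-SNE embedding of a 10-parameter fold-change matrix;
    housekeeping-gene count normalization, differential expression, PCA-loading
    gene selection, gene-expression-signature (GES) scoring, ROC/Youden cutoff
    and Kaplan-Meier/log-rank validation; spatial cytotoxic-T-cell-to-tumor and
    CTL-to-Treg distance statistics from phenotype-labeled cell tables; and a
    seeded synthetic-cohort generator with a replicate-arm equivalence
    simulation for end-to-end testing at the scale of the original study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival
Config/testthat/edition: 3
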