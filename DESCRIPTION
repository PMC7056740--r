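Package: tcd4gate
Title: Hierarchical Gating, Automated Classification and Reference Intervals
    for a 14-Color CD4+ T-Cell Immune Monitoring Panel
Version: 0.1.0
Authors@R:
    person("tcd4gate", "developers", email = "tcd4gate@example.org",
           role = c("aut", "cre"))
Description: An open engine for single-tube immunophenotyping of human blood
    CD4+ T cells with a standardized 14-marker flow cytometry panel. Reads and
    writes FCS 3.0/3.1 list-mode files, applies spillover compensation and
    logicle/asinh scaling, discretizes marker expression into phenotype codes,
    and classifies every event through a deterministic hierarchical gating
    taxonomy of >= 89 reportable CD4+ T-cell populations (classical T-helper
    subsets by chemokine-receptor codes, regulatory T cells, follicular helper
    T cells, and their naive/memory maturation stages). Also provides
    PCA-based maturation-pathway staging, database-guided automated gating
    with a minimum-cluster reporting rule, agreement metrics (r-squared and
    mean normalized bias), canonical variate analysis, age-banded percentile
    reference intervals with profile flagging, exact Mann-Whitney group
    comparison, a stain-index QC utility, and a seeded synthetic whole-blood
    sample simulator with ground-truth labels for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
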