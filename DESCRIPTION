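Package: phosphosig
Title: Phospho-/Proteome Differential Analysis and Minimal Biomarker
    Signature Discovery for LRRK2 Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Re-usable pipeline for discovering blood phospho-/proteome
    biomarkers in clinical cohorts carrying LRRK2 mutations. Implements
    DIA-style intensity-table preprocessing (peptide-count and missingness
    filters, PTM site-level collapse at a localization-confidence cutoff,
    KNN imputation, log2 transformation, quantile normalization),
    empirical-Bayes moderated differential testing with
    Benjamini-Hochberg FDR control, an ANOVA cross-group screen, a Monte
    Carlo tree-search (MCTS) minimal-feature signature search scored by
    SMOTE-balanced cross-validated balanced accuracy, one-vs-rest ROC
    evaluation, and Spearman correlation of differential features with
    clinical motor severity. A seed-reproducible synthetic cohort
    generator with planted effects makes every stage testable without
    access to the original mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    e1071,
    jsonlite,
    pROC,
    stats,
    utils,
    withr
Suggests:
    limma,
    randomForest,
    testthat (>= 3.0.0),
    xgboost
Config/testthat/edition: 3
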