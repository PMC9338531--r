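Package: concordmap
Title: Proteotranscriptomic Concordance, Splicing Landscape and Biomarker
    Screening for Lymphoma Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for matched proteome/transcriptome cohorts of
    ocular adnexal B-cell lymphoma and similar three-arm (normal,
    inflammation, tumor) designs. Computes per-sample global protein-mRNA
    concordance (Spearman rho over matched pairs) and its associations with
    clinical covariates and survival endpoints; classifies cross-layer
    differential-expression concordance; builds an inflammation-independence
    protein signature from nine trend patterns and k-means trajectory
    clusters; calls aberrant alternative-splicing events from inclusion-level
    tables, screens them for progression association, and ranks candidate
    splicing regulators by correlation; and runs a multi-stage diagnostic
    biomarker funnel (differential expression, univariate logistic screen,
    repeated cross-validated lasso, stepwise refinement, ROC benchmarking).
    Includes a synthetic-cohort generator with planted ground truth for
    end-to-end recovery testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    glmnet,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr,
    optparse
Config/testthat/edition: 3
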