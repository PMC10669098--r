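Package: subtme
Title: Tumor Microenvironment Subtyping from Single-Cell and Bulk Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Discovers tumor-microenvironment subtypes (subTMEs) as modules of
    cell subtypes whose per-sample relative abundances co-vary across tumor
    samples, scores them in single-cell and bulk expression data via
    expressing-cell-fraction signature genes and single-sample gene set
    enrichment, prioritizes ligand-receptor interactions between cell subtypes
    by label-permutation significance and cross-pair specificity, and builds
    univariate-Cox linear risk models with Kaplan-Meier and time-dependent ROC
    evaluation. Includes a synthetic-cohort generator with planted abundance
    modules, marker genes, ligand-receptor pairs, and survival signal so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    stats,
    survival,
    utils
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
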