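Package: zygoct
Title: Zygosity Expression Signatures from Low-Density qPCR Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification and classification pipeline for TaqMan low-density
    array (TLDA) and related qPCR expression data, built around KIT-mutation
    zygosity signatures in cell-line panels and gastrointestinal stromal
    tumour (GIST) cohorts. Implements threshold-cycle (Ct) cut-off filtering,
    per-card global-median normalization ("virtual housekeeping gene"),
    delta-delta-Ct relative quantification against the per-assay mean,
    reference-gene Ntarget quantification with per-tumour correcting factors,
    geNorm-style reference-gene stability ranking, high-density array median
    normalization with negative-control detection thresholds and fold-change
    gene selection, control-line nonspecific filtering, ANOVA and PCA feature
    selection, hierarchical clustering with missingness-aware Euclidean
    distances, dendrogram topology checks, and a synthetic Ct-data generator
    that provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    mclust,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
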