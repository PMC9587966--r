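Package: mrtime
Title: Multi-Region Tumour Immune Microenvironment Heterogeneity and
    Co-Evolution Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of tumour immune microenvironment (TIME) heterogeneity
    and co-evolution across multi-region samples of normal tissue, primary
    tumour, metastases and blood. Computes T-cell receptor (TCR) repertoire
    diversity (richness, Shannon entropy, clonality, highly expanded clones,
    depth- and T-cell-fraction-normalized richness), clonotype sharing and
    heterogeneity (Jaccard) across within-patient comparison categories,
    immune-cell infiltration divergence (Euclidean distance on CIBERSORT-style
    fractions), immunomodulator and immunotherapy-biomarker summaries,
    genomic summaries (tumour mutational burden, chromosome instability score,
    trunk/shared/private mutation classes), and a co-evolution test comparing
    complete-linkage dendrograms of neoantigen, TCR and infiltration profiles
    via cophenetic correlation with a permutation p-value. A seeded synthetic
    multi-region cohort generator lets every stage run without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
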