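Package: heterosisDGE
Title: Tag-Based Digital Gene Expression Analysis of Heterosis in Maize Hybrid Trios
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of NlaIII/MmeI (CATG + 17 nt) digital gene expression tag
    libraries from two inbred parents and their F1 hybrid. Implements tag
    cleaning, a virtual CATG+17 tag library over a reference transcriptome with
    tiered exact/1-mismatch mapping, TPM normalization, the Audic-Claverie
    exact test for two-library tag counts with Benjamini-Hochberg control,
    classification of per-gene mode of gene action (additivity, high- and
    low-parent dominance, over- and under-dominance), presence-absence
    expression patterns and PAV cross-referencing, hypergeometric term
    enrichment with Storey q-values, and a fully seeded synthetic-data
    generator with ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    data.table,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
biocViews: GeneExpression, DifferentialExpression, Sequencing, Transcriptomics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
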