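Package: somaSift
Title: Tumor-Only Somatic Variant Classification, Mutational Signatures, and
    Benign-Tissue Cancer Risk Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for extracting somatic genetic risk information from
    benign-tissue whole-exome variant calls made without matched normal DNA.
    Provides panel-of-normals and depth filtering, machine-learning
    classification of somatic versus germline variants from a 31-feature
    schema, allele-frequency concordance validation against genotyping
    arrays, trinucleotide mutational-signature discovery by non-negative
    matrix factorization with residual-sum-of-squares rank selection and
    cosine matching to reference catalogs, covariate-adjusted
    exposure-phenotype association, case-control gene and hotspot
    enrichment with false-discovery-rate control, gene-level copy-number
    deletion calls and deletion-signature association, and protein-domain
    mutation-burden risk models evaluated by bootstrapped AUC. A fully
    seeded synthetic-data generator emulates the statistical structure of
    a benign breast biopsy case-control cohort and supplies ground truth
    for recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    glmnet,
    randomForest,
    e1071,
    xgboost,
    nnet,
    class,
    pROC,
    clue,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
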