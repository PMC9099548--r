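Package: nodalsig
Title: Lymph-Node Metastasis Expression-Signature Discovery for Endometrioid Endometrial Carcinoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a complete bulk RNA-seq workflow for
    discovering a lymph-node-metastasis gene-expression signature in
    endometrioid endometrial carcinoma (EEC) from FFPE tumor samples:
    sample-level quality filtering, voom-weighted moderated-t differential
    expression with Benjamini-Hochberg control, SD-cutoff-selected hierarchical
    clustering with subsampled consensus clustering, nearest-shrunken-centroid
    signature discovery with cross-validation, an MSE-based centroid validator
    with randomization significance, hypergeometric over-representation
    analysis against GMT gene-set collections, and exact r-by-c Fisher /
    Welch-t clinico-pathological group comparisons. A negative-binomial
    synthetic-data generator emulating the 28-sample (16 N+ / 12 N-) study
    cohort makes every stage testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    data.table,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    limma,
    mclust,
    jsonlite
Config/testthat/edition: 3
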