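Package: oncostates
Title: Cell-State Decomposition and Enrichment Analysis for
    Oncogene-Induced Lung Cell Plasticity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Downstream transcriptomic characterization of
    oncogene-induced dual-identity lung epithelial cells: derivation of
    cell-type gene signatures from reference expression panels,
    single-sample gene-set enrichment (rank-normalized weighted ECDF
    difference), information-coefficient association with empirical
    permutation significance, non-negative matrix factorization for
    sample clustering, Onco-GPS style two-dimensional state maps with
    projection of new samples, and small bespoke quantifications
    (delta-delta-CT fold change, marker-gated population fractions).
    A synthetic-data module with planted gene programs makes every
    stage testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
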