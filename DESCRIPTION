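Package: ectoMark
Title: Ectopic Gene Activation Biomarker Discovery for Tumour Prognosis
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery and validation of prognostic biomarkers based on the
    ectopic activation, in tumours, of genes that are normally silent in
    adult non-germline somatic tissues. Provides cataloguing of
    tissue-predominant silent genes from a normal-tissue expression panel,
    a survival-linked percentile-threshold stability screen (Cox association,
    log-rank threshold scan, significant-interval width), binary activation
    calling, an activation-count panel classifier with subgroup and
    multivariate survival analyses, composite immunohistochemistry scoring,
    differential-expression signatures with a running-sum gene set
    enrichment engine, and fully seeded synthetic-cohort generators with
    ground-truth records for end-to-end validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    survival,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
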