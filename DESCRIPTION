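Package: tmeclass
Title: Tumour-Microenvironment-Based Molecular Subtyping of High-Grade
    Serous Ovarian Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised discovery of immune and non-immune classes in bulk
    expression cohorts of high-grade serous ovarian cancer by consensus
    non-negative matrix factorization, refinement into activated-immune and
    CAFs-immune subtypes by single-sample immune/stromal enrichment, a
    marker-template subtype classifier projected into new cohorts by nearest
    template prediction, and the accompanying immunogenomic, epigenetic,
    drug-response and outcome analyses. Ships a synthetic multi-omic cohort
    generator with planted ground truth so the whole pipeline is testable
    end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
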