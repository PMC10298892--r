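Package: dualscreen
Title: Dual-Evidence Candidate Gene Prioritization from Chemical and
    Copy-Number Screens
Version: 1.0.0
Authors@R:
    person("Package", "Author", role = c("aut", "cre"),
           email = "author@example.com")
Description: Integrates a phenotypic chemical screen (persistent
    buccopharyngeal membrane in Xenopus laevis embryos) with
    copy-number-deletion data from patients with Choanal Atresia to
    nominate candidate regulator genes. Provides strict readers for
    screen, chemical-target, CNV, gene-annotation and functional-category
    tables; hit calling from per-embryo phenotype scores; chemical target
    deconvolution with distinct-hit-chemical frequency ranking; deletion
    interval to gene mapping with per-patient recurrence counting;
    functional-category profiling and cross-arm shared categories;
    focused-list intersection with full provenance; and seeded
    synthetic-data generators with planted signals for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    IRanges,
    jsonlite,
    readr,
    tibble,
    tools,
    utils,
    stats,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
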