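Package: odysseycost
Title: Micro-Costing of the Rare-Disease Diagnostic Odyssey and Trio
    Whole-Genome Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A micro-costing toolkit for health-economic evaluation of
    genomic diagnostics in rare disease. Costs each proband's standard
    genetic-testing "sub-odyssey" from a unit-cost registry with an
    amplicon/exon-bin fallback price, adds hospital-attendance costs and
    summarises cohorts by rare-disease category with Tukey-fence outlier
    flagging; builds a stage-based per-trio cost ledger for trio
    whole-genome sequencing from staff time, batch-amortised consumables,
    annuitized capital (annual equivalent cost at a fixed discount rate),
    probability-weighted branches and VAT-bearing external charges; and
    summarises interview willingness-to-pay and attribute-rating data.
    Includes a calibrated synthetic-cohort generator (truncated lognormal
    costs, zero-truncated negative-binomial test counts) so the whole
    pipeline is testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
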