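Package: raremix
Title: Gene-Based Association Tests Combining Rare and Common Variants
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Gene-based association testing for quantitative traits in exome
    sequence data. Implements three rare-variant collapsing tests (fixed
    threshold, Madsen-Browning weighted, and variable threshold) with
    permutation significance, two common-variant gene tests (per-gene minimum
    p-value and LASSO model selection by a Mallows Cp analog), a Fisher's
    method combination of the rare and common signals within a gene, and
    mean-ratio genomic-control correction of inflated test families. A
    cohort simulator with a two-subpopulation ancestry confounder and an
    evaluation harness estimate power and type I error across phenotype
    replicates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    glmnet,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
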