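Package: omicsfunnel
Title: Integrative Variant-Expression-Pathway Funnel for Case-Control Omics Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Integrates per-sample variant calls, differential-expression tables and
    pathway gene sets for case-control disease modelling. Implements cross-case
    variant intersection, differential-expression and pathway over-representation
    filtering, verification-cohort rules, a chi-square test battery (Pearson,
    Yates-corrected and goodness-of-fit) that classifies variants into putative
    mutations versus putative effect modifiers, EM haplotype-frequency estimation
    with D, D-prime and r-squared linkage disequilibrium, hub-gene and pathogenic
    pathway prioritisation, and a TargetScan-style microRNA seed-site scanner.
    Ships a deterministic synthetic-cohort generator with planted ground truth so
    every stage of the pipeline has a recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    withr,
    vcfR,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
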