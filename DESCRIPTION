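Package: mitorder
Title: Comparative Analysis of Mitochondrial Gene-Order Rearrangements in Snakes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparing circular mitochondrial gene orders across
    snake lineages. Provides canonical rotation-invariant comparison of
    annotated gene orders, assignment of arrangement-type labels against a
    reference registry, rule-based detection of rearrangement features
    (light-strand replication origin loss, control-region duplication and
    asymmetry, tRNA translocations, pseudogenes, non-coding insertions),
    Fitch parsimony reconstruction of arrangement characters on a rooted
    phylogeny with DELTRAN-style resolution, inference of event paths
    between arrangements, and a seeded generator of fully annotated
    synthetic mitogenome records for every arrangement type so the whole
    pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
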