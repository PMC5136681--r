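Package: taxalign
Title: Alignment and Faceted Comparison of Multiple Taxonomic Hierarchies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Merges two or more rooted taxonomic hierarchies into a single
    composite "aligner" tree using conservative scientific-name-literal
    matching, computes a synchronized row layout that places equivalent name
    usages on shared rows across checklists, classifies every name literal
    into comparison facets (common, different, missing, inconsistent,
    potential synonyms), and exports the comparison as CSV or Excel
    workbooks. Reads Darwin Core style checklist tables and nested JSON
    trees, ships deterministic fixture generators with controlled overlap
    and inconsistency, and includes a network-optional client for GBIF
    Species API style name-usage queries backed by recorded fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    utils,
    zip
Suggests:
    httr,
    optparse,
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
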