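Package: methpanel
Title: Discovery of Tumor-Hypermethylated CpG Marker Panels from
    Methylation Array Beta Values
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements an in-silico workflow for discovering CpG marker
    panels hypermethylated in tumors from methylation-array beta-value
    matrices: per-CpG differential methylation (delta-beta with
    Benjamini-Hochberg correction), CpG-island restriction, exclusion of
    blood-methylated and epigenetic-clock probes, a two-branch panel
    selection cascade, pan-cancer specificity classification across many
    tumor-type cohorts, and concordance of CpG location (promoter versus
    gene body) with host-gene expression changes. Includes a seeded
    synthetic-data generator that emulates the statistical structure of
    multi-cohort methylome and RNA-seq inputs with planted probe classes
    and a ground-truth table, so the full pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
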