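Package: shhland
Title: Post-Caller Genomic Evidence Integration for Shh-Medulloblastoma-Style Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates the outputs of upstream fusion, copy-number and variant
    callers for sonic-hedgehog medulloblastoma style tumor cohorts. Provides
    blacklist construction from control RNA-seq libraries and a fusion filter
    cascade (readthrough, circular-RNA, expression-ratio and junction-proportion
    rules), structural-variant support tiering of fusions from WGS breakpoints
    and SNP-array copy-number breakpoints, copy-number segment merging and
    germline-CNV filtering with gene-level state assignment, Kruskal-Wallis
    detection of copy-number-responsive genes, promoter-methylation driver
    detection via beta-value mixture models, a post-annotation RNA-seq somatic
    variant filter cascade, and co-occurrence/mutual-exclusivity testing of
    driver alterations. Ships a synthetic cohort generator with planted ground
    truth so every stage is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mclust,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
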