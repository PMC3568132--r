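Package: exomesieve
Title: Family-Based Rare-Variant Filtering and Prioritization for Exome Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for prioritizing rare germline variants in multiplex
    disease families sequenced by whole-exome sequencing. Implements
    pre-alignment read quality filters, per-variant depth and quality
    scores (DS/QS) computed as allele ratios, a staged filtering cascade
    (within-family sharing, control-panel and known-variant exclusion,
    functional consequence, score and gene filters) with per-stage funnel
    summaries, score-threshold calibration against database-member truth
    sets, rare-variant case-control association (two-sided Fisher exact
    test, odds ratios with Woolf confidence intervals), minor allele
    frequency screening, pedigree segregation and phenocopy evaluation,
    and candidate prioritization. A synthetic-data module generates reads,
    family variant sets, exclusion site sets and case-control cohorts with
    known truth, so every stage of the pipeline can be exercised and
    validated without access to protected sequencing data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    S4Vectors,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
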