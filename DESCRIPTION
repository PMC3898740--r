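Package: vtburden
Title: Variable-Threshold Rare-Variant Burden Testing with Permutation
    Adjustment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Case-control enrichment analysis of rare coding variants in a
    single gene. Qualifies variants by functional class, protein-domain
    region and sample minor-allele-frequency threshold, collapses carriers
    under dominant or additive genetic models into 2x2 tables, computes
    exact two-sided Fisher p-values by hypergeometric enumeration, scans a
    ladder of MAF thresholds for the minimum p-value statistic, and adjusts
    that statistic for threshold selection by case/control label
    permutation. Includes region-restricted and merged-cohort analyses, a
    synthetic cohort simulator with Hardy-Weinberg genotypes and a
    configurable case-enrichment odds ratio, and calibration/power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
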