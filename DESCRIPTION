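Package: acmgrare
Title: ACMG/AMP Classification of Rare Recessive Variants with
    Case-Control Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Evaluates ACMG/AMP pathogenicity criteria for rare variants in
    autosomal-recessive disease genes from population allele-frequency
    records (PM2, BA1, BS1), in silico predictor consensus over a 16-tool
    panel (PP3, BP4), gene-level variant-class summaries (PP2, BP1), and
    pedigree co-segregation (PP1, BS4); computes rare-variant case-control
    enrichment as a Haldane-Anscombe-corrected odds ratio with a
    Bonferroni-adjusted Wald confidence interval (PS4); and combines met
    evidence into the five-tier classification (pathogenic, likely
    pathogenic, uncertain significance, likely benign, benign) with an
    auditable rule trace.  Includes readers for PED pedigrees and tabular
    cohort/frequency/predictor inputs, a synthetic cohort and pedigree
    generator for end-to-end testing, and a worked inherited-retinal-
    dystrophy cohort built from published summary tables for two RPE65
    missense variants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
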