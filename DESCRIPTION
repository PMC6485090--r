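Package: oncotier
Title: Tiered Somatic Variant Curation and Therapy Matching for Tumor
    Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Actionability tiering of somatic variants against a
    clinical-evidence knowledge base, RNA-based annotation (modified
    z-score expression outliers, percent-spliced-in exon-skipping
    detection, DNA-RNA allele-fraction concordance), tumor-purity-corrected
    copy-number prioritization, drug and combination-therapy matching with
    a hypermutation checkpoint-inhibitor rule, and call-set concordance
    statistics (sensitivity, positive predictive value, germline-miscall
    audits), together with a seeded synthetic glioblastoma-like cohort
    generator and observer models for panels and automated curators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    withr,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
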