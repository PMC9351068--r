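Package: clonemap
Title: Clonality Inference and Parental-Allele Chromosome Mapping for
    Multifocal Tumor Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of multi-region and multifocal tumor
    sequencing cohorts, motivated by multifocal ileal neuroendocrine tumors.
    Implements post-calling filters for somatic small variants, copy-number
    segments and structural variants; allele-specific chromosome mapping of
    copy-number alterations from heterozygous-SNP allelic read counts (exact
    binomial test with per-segment Benjamini-Hochberg correction); clonality
    inference from shared somatic variants (independence of synchronous
    primaries, metastasis origin assignment, clonal versus independent
    dissemination); cohort-level recurrence summaries and hypergeometric
    pathway enrichment; and a seeded synthetic-cohort simulator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    vcfR,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
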