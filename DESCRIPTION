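Package: triotriage
Title: Clinical Variant Triage for Parent-Offspring Trio Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated triage of annotated variant calls from parent-offspring
    trios against a genotype-to-phenotype gene panel, in the style of large
    diagnostic sequencing studies of developmental disorders. Implements
    frequency and functional-consequence filtering, Mendelian inheritance
    classification from trio genotypes, allelic-requirement matching
    (dominant, recessive homozygous, compound heterozygous, X-linked),
    copy-number variant dosage and size rules, and cohort-level reporting of
    predictive value and diagnostic yield. Ships a seeded synthetic trio
    cohort generator with spike-in truth tables so every pipeline stage can
    be exercised offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
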