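Package: qvtools
Title: Qualifying Variant Criteria Files and Their Evaluation Engine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Read, write, validate, build and checksum qualifying-variant (QV)
    criteria documents: portable, versioned YAML or JSON files that externalize
    variant filtering and interpretation rules from pipeline code. Applies QV
    filters and criteria to VCF-derived variant tables with three-valued
    (pass/fail/missing) condition logic, per-sample aggregation for trio-style
    quality filters, and BED panel-overlap restriction. Includes cohort quality
    control (call rates, minor allele frequency, an exact Hardy-Weinberg
    equilibrium test), ACMG-style criterion flags including compound
    heterozygosity, a local SHA-256 release registry, seeded synthetic cohort and
    trio generators with truth tables, and an independent hard-coded oracle
    filter path for equivalence testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    digest,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    openssl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
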