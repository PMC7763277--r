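Package: irdtriage
Title: Pedigree-Aware Variant Prioritization for Inherited Retinal Dystrophies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multi-strategy diagnostic toolkit for inherited retinal
    dystrophies (IRD). Implements a pedigree-aware variant prioritization
    cascade (frequency, consequence, zygosity/compound-heterozygote pairing,
    control-genotype and ACMG evidence-combining filters, with recovery
    rules and a lax re-analysis mode), coverage-ratio copy-number calling,
    Mendelian co-segregation checking (including 47,XXY karyotypes),
    X-chromosome microsatellite haplotype reconstruction with shared-region
    detection, and a panel/clinical-exome/whole-exome sequencing strategy
    comparator (per-sample output, cost, first-line diagnostic yield).
    Ships seeded synthetic-family generators with planted causal genotypes
    so every stage is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    purrr,
    readr,
    rlang,
    stringr,
    ggplot2,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
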