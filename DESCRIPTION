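Package: tissueASE
Title: Multi-Tissue Allele-Specific Expression Calling, Classification
    and Cohort Contrasts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls allele-specific expression (ASE) at heterozygous sites
    per tissue with an exact binomial test against an empirically estimated
    reference-mapping bias, applies the standard quality-control filter
    cascade (allele and total depth, bi-allelic expression, intragenic
    location, significance), classifies sites into no/shared/variable ASE
    across tissues from the mean and dispersion of allelic ratios, detects
    monoallelic expression, quantifies technical-replicate concordance and
    classification reproducibility over cutoff grids, and tests
    cohort-level contrasts (deleterious and nonsense versus control
    alleles, rare versus common nonsense alleles as a nonsense-mediated
    decay signal). Ships a beta-binomial simulator of multi-tissue,
    multi-replicate allele counts with configurable mapping bias, depth
    regimes, overdispersion and ground-truth ASE classes, so every stage
    is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
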