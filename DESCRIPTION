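Package: pahpanel
Title: Long-Amplicon Nanopore Panel Analysis for PAH/Phenylketonuria Diagnostics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the analysis behind a long-amplicon Oxford Nanopore
    panel for molecular diagnosis of phenylketonuria (PKU): in-silico PCR
    validation of a multiplexed PAH primer panel (primer-site search,
    amplicon enumeration, target coverage, pool assignment), parsing of the
    HGVS c.-notation subset used in clinical PAH reports, allele-fraction
    based zygosity calling with a data-derived homozygosity threshold,
    genotype-to-phenotype classification via allelic/genotypic phenotype
    values (APV/GPV), cohort-level variant-frequency statistics, and a
    beta-binomial pileup simulator with known truth for benchmarking. Ships
    a 40-patient PKU cohort fixture as a plain-text table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
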