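Package: invkit
Title: Detection and Population-Genetic Analysis of Polymorphic Chromosomal Inversions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect large polymorphic chromosomal inversions from
    multi-sample SNP genotype matrices by principal component analysis,
    assign per-individual karyotypes and localize breakpoint blocks from
    PC1 loadings, verify breakpoints from linked-read barcode-interaction
    calls with distance/quality/gap/support filters, classify ancestral
    versus derived arrangements from heterozygosity, shared-polymorphism
    and fixed-difference rates against an outgroup, test whether observed
    derived-allele frequencies exceed neutral site-frequency-spectrum
    expectations by permutation, and estimate and meta-summarize
    standardized karyotype effects on fitness-related traits. Includes a
    synthetic-data generator producing genotype, linked-read, outgroup,
    tag-SNP and phenotype data with known truth for parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lme4,
    purrr,
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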