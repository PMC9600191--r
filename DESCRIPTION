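Package: csfgi
Title: Genomic Instability Scoring for Cerebrospinal-Fluid Cell-Free DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies genomic instability in liquid-biopsy samples from the
    allele fractions of shared germline heterozygous variants. Matched
    leukocyte, plasma and cerebrospinal-fluid variant tables are screened for
    shared germline mutations; the GI score of a sample is the proportion of
    those mutations whose allele fraction falls outside the theoretical
    quartile band around 0.5, and samples are classified genomically unstable
    (GI) or stable (GS) by a data-driven mixture-model cutoff. Includes a
    binned log2-ratio copy-number validation arm, cohort-level statistics
    (group comparisons, Kaplan-Meier and Cox survival, co-mutation
    enrichment), and a fully seeded synthetic-cohort generator that emulates
    allele-specific copy-number driven allelic imbalance at a given tumor
    fraction.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
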