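Package: histocompat
Title: Mother-Child Histocompatibility Classification and Case-Control
    Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies children as histocompatible from the mother's
    perspective at classical HLA loci and HLA-restricted minor
    histocompatibility antigen (mHag) SNPs by inferring the paternally
    inherited allele from unphased mother-child genotypes; scores
    mother-child allele similarity with a positional amino-acid sequence
    similarity matching (SSM) function and control-based quartiles; and
    provides the case-control association layer used in autoimmune-disease
    epidemiology (covariate-adjusted logistic odds ratios with Wald
    intervals, crude odds ratios, two-sided Fisher's exact tests,
    Bonferroni correction, ordinal trend tests, and missingness
    chi-square tests). Includes a synthetic cohort generator with
    Hardy-Weinberg mating, Mendelian transmission, a parity confounder,
    a logistic disease model, and configurable missingness so every
    pipeline stage is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
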