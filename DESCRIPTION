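Package: rrpat
Title: Robust Reference Powered Association Tests for Case-Control GWAS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Case-control genome-wide association testing that borrows a large
    public reference panel (for example gnomAD population allele counts) as
    auxiliary controls while remaining robust to control-reference
    differentiation. Implements the statistic T = ln P(ca-(co+re)) -
    ln P(co-re), the difference of the log p-values of two Fisher exact
    tests, which is Laplace(0,1) distributed under the null of equal allele
    frequencies, together with its closed-form one-tail p-value and a
    reference-compatibility gate. Includes exact log-space Fisher and
    Hardy-Weinberg tests, Monte-Carlo type-I-error and power simulation over
    a factorial scenario grid, a per-SNP pipeline (reference joining with
    allele reconciliation, HWE filtering, Bonferroni thresholds, genomic
    inflation, rescued-SNP classification), readers and writers for VCF and
    TSV inputs, and a synthetic cohort generator with controllable
    stratification for end-to-end testing.
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
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
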