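# Independent brute-force oracles, deliberately written on a different
# numerical route (plain choose() products in probability space) than the
# package's log-space implementations.

# Two-sided Fisher p-value by exhaustive hypergeometric enumeration:
# sum the probabilities of every table with the observed margins whose
# probability does not exceed the observed table's (1 + 1e-7 tie tolerance).
fisher_oracle <- function(alt_a, total_a, alt_b, total_b) {
  k <- alt_a + alt_b
  sup <- max(0, k - total_b):min(k, total_a)
  probs <- choose(total_a, sup) * choose(total_b, k - sup) /
    choose(total_a + total_b, k)
  obs <- probs[sup == alt_a]
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

# Exact HWE p-value by brute-force enumeration over every heterozygote count
# of matching parity, probabilities via plain factorial ratios.
hwe_oracle <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  na <- 2 * n_hom_alt + n_het          # alt allele copies
  r <- min(na, 2 * n - na)
  if (r == 0) return(1)
  sup <- seq(r %% 2, min(r, 2 * n - r), by = 2)
  probs <- vapply(sup, function(h) {
    exp(h * log(2) + lfactorial(n) - lfactorial((r - h) / 2) -
          lfactorial(h) - lfactorial(n - h - (r - h) / 2) +
          lfactorial(r) + lfactorial(2 * n - r) - lfactorial(2 * n))
  }, numeric(1))
  obs <- probs[sup == n_het]
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

# Standard Laplace(0,1) CDF, the null distribution of T
laplace_cdf <- function(t) ifelse(t < 0, 0.5 * exp(t), 1 - 0.5 * exp(-t))

# small ready-made count table for pipeline tests
toy_snps <- function(n = 6, seed = 99) {
  withr::with_seed(seed, {
    q <- runif(n, 0.1, 0.4)
    tibble::tibble(
      chrom = "1", pos = 1000L + seq_len(n), rsid = sprintf("rs%d", seq_len(n)),
      ref = "A", alt = "G",
      case_alt = rbinom(n, 200, q), case_total = 200L,
      control_alt = rbinom(n, 200, q), control_total = 200L,
      ref_alt = rbinom(n, 4000, q), ref_total = 4000L
    )
  })
}
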