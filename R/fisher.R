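#' Two-sided Fisher exact test for 2x2 allele-count tables
#'
#' Exact p-value for comparing the allele counts of two groups at one biallelic
#' site, i.e. the 2x2 table
#' \preformatted{  alt_a   total_a - alt_a
#'   alt_b   total_b - alt_b}
#' Vectorized over sites: all four arguments are recycled to a common length
#' and one p-value is returned per table. The two-sided p-value follows the
#' minimum-likelihood rule used by [stats::fisher.test()]: it sums the
#' hypergeometric probabilities of all tables (with the observed margins) that
#' are no more probable than the observed one, with the same `1 + 1e-7`
#' relative tolerance for ties. Computation is carried out in log space, so
#' `log.p = TRUE` stays accurate for p-values far below `1e-300` — the regime
#' reached when a study is compared against a reference panel of tens of
#' thousands of chromosomes.
#'
#' A table where one margin is zero (for example both groups monomorphic for
#' the same allele) admits a single outcome and returns 1.
#'
#' @param alt_a,total_a Copies of the tested allele and total chromosome count
#'   (2N) in the first group.
#' @param alt_b,total_b The same for the second group.
#' @param alternative `"two.sided"` (default, the GWAS convention), `"less"`
#'   (alt allele rarer in the first group) or `"greater"`.
#' @param log.p Return the natural log of the p-value.
#' @return Numeric vector of p-values in (0, 1], or their logs.
#' @examples
#' fisher_exact_2x2(1, 10, 9, 10)               # strong imbalance
#' fisher_exact_2x2(5, 10, 5, 10)               # identical groups -> 1
#' fisher_exact_2x2(c(30, 15), 400, 200, 400)   # vectorized
#' @export
fisher_exact_2x2 <- function(alt_a, total_a, alt_b, total_b,
                             alternative = c("two.sided", "less", "greater"),
                             log.p = FALSE) {
  alternative <- match.arg(alternative)
  n <- max(length(alt_a), length(total_a), length(alt_b), length(total_b))
  alt_a <- rep_len(as.numeric(alt_a), n)
  total_a <- rep_len(as.numeric(total_a), n)
  alt_b <- rep_len(as.numeric(alt_b), n)
  total_b <- rep_len(as.numeric(total_b), n)
  if (anyNA(c(alt_a, total_a, alt_b, total_b))) {
    stop("allele counts must not contain NA")
  }
  if (any(total_a < 1) || any(total_b < 1)) {
    stop("empty group: chrom_total must be >= 1")
  }
  if (any(alt_a < 0) || any(alt_b < 0) || any(alt_a > total_a) ||
      any(alt_b > total_b)) {
    stop("alt_count must lie in [0, chrom_total]")
  }
  out <- numeric(n)
  # group tables sharing margins so the hypergeometric support is enumerated
  # once per (total_a, total_b, k) rather than once per table
  grp <- split(seq_len(n), paste(total_a, total_b))
  for (idx in grp) {
    out[idx] <- fisher_log_p_margins(alt_a[idx], alt_a[idx] + alt_b[idx],
                                     total_a[idx][1L], total_b[idx][1L],
                                     alternative = alternative)
  }
  if (log.p) out else exp(out)
}

# Log two-sided (or one-sided) Fisher p-values for tables with common margins
# n1, n2: x successes in group 1, k total successes. Vectorized over (x, k).
fisher_log_p_margins <- function(x, k, n1, n2,
                                 alternative = "two.sided") {
  out <- numeric(length(x))
  if (alternative == "less") {
    return(phyper(x, n1, n2, k, lower.tail = TRUE, log.p = TRUE))
  }
  if (alternative == "greater") {
    return(phyper(x - 1, n1, n2, k, lower.tail = FALSE, log.p = TRUE))
  }
  log_relerr <- log(1 + 1e-7)
  for (kk in unique(k)) {
    idx <- which(k == kk)
    lo <- max(0, kk - n2)
    hi <- min(kk, n1)
    if (lo == hi) {            # single admissible table -> p = 1
      out[idx] <- 0
      next
    }
    sup <- lo:hi
    lp <- dhyper(sup, n1, n2, kk, log = TRUE)
    lps <- sort(lp)
    obs <- lp[x[idx] - lo + 1L]
    pos <- findInterval(obs + log_relerr, lps)
    out[idx] <- pmin(logsumexp_head_sorted(lps, pos), 0)
  }
  out
}

# log(sum(exp(lx[1:pos]))) for an ascending-sorted log vector lx, evaluated at
# each queried position. The fast path, cumsum(exp(lx - max)), loses terms
# that underflow relative to the global maximum; queried positions that deep
# in the tail are recomputed against their own local maximum, which is exact
# because the vector is sorted.
logsumexp_head_sorted <- function(lx, pos) {
  m <- lx[length(lx)]
  cs <- cumsum(exp(lx - m))
  out <- m + log(cs[pos])
  bad <- which(lx[pos] - m < -690)
  for (j in bad) {
    i <- pos[j]
    out[j] <- lx[i] + log(sum(exp(lx[seq_len(i)] - lx[i])))
  }
  out
}
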