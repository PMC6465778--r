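#' The reference-powered test statistic T
#'
#' `t_statistic()` computes `T = ln(p_ca_core) - ln(p_co_re)`, the difference
#' of the log p-values of the case-vs-(control+reference) and the
#' control-vs-reference Fisher exact tests. Under the null hypothesis that
#' case, control and reference share one allele frequency, both component
#' p-values are (approximately) Uniform(0,1) and independent, so their
#' negative logs are Exponential(1) and T follows a standard Laplace(0,1)
#' distribution. Large negative T means the case-vs-pool difference dominates;
#' large positive T means control-reference differentiation dominates.
#'
#' @param p_ca_core P-value of the case vs pooled control+reference test,
#'   in (0, 1].
#' @param p_co_re P-value of the control vs reference test, in (0, 1].
#' @return Numeric vector of T values.
#' @seealso [p_of_t()] for the one-tail p-value of T, [rrpat_test()] for the
#'   full per-SNP test.
#' @examples
#' t_statistic(0.01, 0.5)
#' t_statistic(exp(-5), exp(-2))  # exactly -3
#' @export
t_statistic <- function(p_ca_core, p_co_re) {
  check_pvalue(p_ca_core)
  check_pvalue(p_co_re)
  log(p_ca_core) - log(p_co_re)
}

#' One-tail p-value of the T statistic
#'
#' Closed-form lower-tail Laplace(0,1) probability of
#' `T = ln(p1) - ln(p2)`, written directly in terms of the two component
#' p-values:
#' \deqn{P(T) = p_1 / (2 p_2)  \quad  (p_1 \le p_2), \qquad
#'       P(T) = 1 - p_2 / (2 p_1) \quad (p_1 > p_2).}
#' The two branches meet continuously at `p1 = p2` where both give 1/2.
#' P(T) is strictly increasing in `p1` and strictly decreasing in `p2`:
#' any growth in control-reference differentiation weakens the claimed
#' significance. The ratio is evaluated in log space so that component
#' p-values near `1e-300` do not overflow the division.
#'
#' Because Fisher exact p-values are discrete (stochastically larger than
#' uniform), P(T) computed from them is conservative under the null rather
#' than exactly Laplace; the exact Laplace calibration holds for continuous
#' uniform inputs.
#'
#' @inheritParams t_statistic
#' @param p_ca_core,p_co_re Component p-values in (0, 1], recycled to a
#'   common length.
#' @return Numeric vector of p-values in (0, 1].
#' @examples
#' p_of_t(0.01, 0.5)   # 0.01
#' p_of_t(0.2, 0.2)    # 0.5 on the branch boundary
#' p_of_t(0.5, 0.01)   # 0.99
#' @export
p_of_t <- function(p_ca_core, p_co_re) {
  check_pvalue(p_ca_core)
  check_pvalue(p_co_re)
  p_of_t_log(log(p_ca_core), log(p_co_re))
}

# log-space core: lp1, lp2 are log p-values (branches evaluated only where
# selected, so the off-branch ratio can never overflow or warn)
p_of_t_log <- function(lp1, lp2) {
  n <- max(length(lp1), length(lp2))
  lp1 <- rep_len(lp1, n)
  lp2 <- rep_len(lp2, n)
  b1 <- lp1 <= lp2
  out <- numeric(n)
  out[b1] <- exp(lp1[b1] - log(2) - lp2[b1])
  out[!b1] <- 1 - 0.5 * exp(lp2[!b1] - lp1[!b1])
  out
}

# -log10 P(T), exact in log space even where p_t underflows double precision
neg_log10_p_of_t <- function(lp1, lp2) {
  n <- max(length(lp1), length(lp2))
  lp1 <- rep_len(lp1, n)
  lp2 <- rep_len(lp2, n)
  b1 <- lp1 <= lp2
  out <- numeric(n)
  out[b1] <- -(lp1[b1] - log(2) - lp2[b1]) / log(10)
  out[!b1] <- -log1p(-0.5 * exp(lp2[!b1] - lp1[!b1])) / log(10)
  out
}

check_pvalue <- function(p) {
  if (anyNA(p) || any(p <= 0) || any(p > 1)) {
    stop("invalid p-value: values must lie in (0, 1]")
  }
  invisible(p)
}

#' Pool two groups of allele counts
#'
#' Componentwise sum of alt-allele copies and chromosome totals, used to pool
#' the control group with the reference panel into the enlarged comparison
#' group of the case-vs-(control+reference) test. Vectorized; commutative.
#'
#' @param alt_a,total_a Allele count and chromosome total of the first group.
#' @param alt_b,total_b Allele count and chromosome total of the second group.
#' @return A tibble with columns `alt_count` and `chrom_total`.
#' @examples
#' merge_counts(10, 1000, 100, 20000)
#' @export
merge_counts <- function(alt_a, total_a, alt_b, total_b) {
  tibble::tibble(alt_count = alt_a + alt_b, chrom_total = total_a + total_b)
}

#' Reference-powered association test per SNP
#'
#' Runs the full test battery on a table of per-SNP allele counts for case,
#' control and reference groups: the three Fisher exact tests
#' (case vs control+reference, control vs reference, case vs control), the
#' statistic `T`, its one-tail p-value `P(T)`, and the reference-compatibility
#' gate `P(co-re) >= gate`. A SNP failing the gate shows control-reference
#' differentiation too strong for the pooled reference to be trusted (e.g.
#' population stratification or genotyping-platform artifacts), and its
#' reference-powered p-value should not be interpreted.
#'
#' @param data A data frame with one row per SNP and numeric columns
#'   `case_alt`, `case_total`, `control_alt`, `control_total`, `ref_alt`,
#'   `ref_total` (alt-allele copies and total chromosomes, 2N, per group).
#'   Any further columns (identifiers, positions) are carried through.
#' @param gate Compatibility threshold on `P(co-re)`; default 0.01.
#' @param alternative Sidedness of the component Fisher tests; two-sided is
#'   the GWAS convention.
#' @return The input tibble with columns appended: `p_ca_core`, `p_co_re`,
#'   `p_ca_co`, `t_value`, `p_t`, `neg_log10_p_t`, `reference_compatible`.
#'   `neg_log10_p_t` is computed in log space and remains finite and exact
#'   where `p_t` underflows double precision.
#' @examples
#' snps <- tibble::tibble(
#'   case_alt = c(30, 60), case_total = 400,
#'   control_alt = c(15, 30), control_total = 400,
#'   ref_alt = c(750, 1500), ref_total = 20000
#' )
#' rrpat_test(snps)
#' @export
rrpat_test <- function(data, gate = 0.01,
                       alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  need <- c("case_alt", "case_total", "control_alt", "control_total",
            "ref_alt", "ref_total")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    stop("missing count columns: ", paste(missing_cols, collapse = ", "))
  }
  check_pvalue(gate)
  pooled <- merge_counts(data$control_alt, data$control_total,
                         data$ref_alt, data$ref_total)
  lp1 <- fisher_exact_2x2(data$case_alt, data$case_total,
                          pooled$alt_count, pooled$chrom_total,
                          alternative = alternative, log.p = TRUE)
  lp2 <- fisher_exact_2x2(data$control_alt, data$control_total,
                          data$ref_alt, data$ref_total,
                          alternative = alternative, log.p = TRUE)
  lp3 <- fisher_exact_2x2(data$case_alt, data$case_total,
                          data$control_alt, data$control_total,
                          alternative = alternative, log.p = TRUE)
  tibble::as_tibble(data) |>
    dplyr::mutate(
      p_ca_core = exp(lp1),
      p_co_re = exp(lp2),
      p_ca_co = exp(lp3),
      t_value = lp1 - lp2,
      p_t = p_of_t_log(lp1, lp2),
      neg_log10_p_t = neg_log10_p_of_t(lp1, lp2),
      reference_compatible = exp(lp2) >= gate
    )
}
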