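#' Join reference allele counts onto study SNPs
#'
#' Matches each study SNP to the reference table by chromosome and position
#' ("chr" prefixes are ignored for matching), then reconciles alleles:
#' \itemize{
#'   \item exact ref/alt match: reference alt count used as is;
#'   \item swapped ref/alt: alt count flipped to `AN - AC`;
#'   \item strand-complement match (alleles reported on the opposite strand):
#'     complemented, then the two rules above;
#'   \item strand-ambiguous study SNPs (A/T or C/G pairs, where a strand flip
#'     is indistinguishable from an allele swap): dropped;
#'   \item no reconcilable reference record: dropped.
#' }
#' Dropped SNPs and their reasons are recorded in the `drop_log` attribute of
#' the result (a tibble with `chrom`, `pos`, `rsid`, `reason`). A site-match
#' rate below 50% raises a warning, the usual symptom of a genome-build
#' mismatch between study and reference.
#'
#' @param snps Study SNP tibble with columns `chrom`, `pos`, `rsid`,
#'   `ref`, `alt` plus count columns (carried through).
#' @param reference Reference tibble with columns `chrom`, `pos`, `ref`,
#'   `alt`, `ac`, `an` (alt-allele count and total allele number), e.g. from
#'   [read_reference()]. Duplicate (chrom, pos, ref, alt) records are an
#'   error.
#' @return The matched study tibble with `ref_alt` and `ref_total` columns
#'   appended and attribute `drop_log`.
#' @export
join_reference <- function(snps, reference) {
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(snps)),
            all(c("chrom", "pos", "ref", "alt", "ac", "an") %in%
                  names(reference)))
  ref <- reference |>
    dplyr::mutate(chrom_key = norm_chrom(.data$chrom)) |>
    dplyr::select(chrom_key, pos_key = "pos", ref_ref = "ref",
                  ref_alt_allele = "alt", ac = "ac", an = "an")
  dup <- ref |>
    dplyr::count(.data$chrom_key, .data$pos_key, .data$ref_ref,
                 .data$ref_alt_allele) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("duplicate reference entries at: ",
         paste(dup$chrom_key, dup$pos_key, sep = ":", collapse = ", "))
  }
  study <- snps |>
    dplyr::mutate(.row = dplyr::row_number(),
                  chrom_key = norm_chrom(.data$chrom))
  cand <- study |>
    dplyr::inner_join(ref, by = c("chrom_key", pos = "pos_key"),
                      relationship = "many-to-many") |>
    dplyr::mutate(
      match_type = dplyr::case_when(
        .data$ref == .data$ref_ref & .data$alt == .data$ref_alt_allele ~ 1L,
        .data$ref == .data$ref_alt_allele & .data$alt == .data$ref_ref ~ 2L,
        complement_allele(.data$ref) == .data$ref_ref &
          complement_allele(.data$alt) == .data$ref_alt_allele ~ 3L,
        complement_allele(.data$ref) == .data$ref_alt_allele &
          complement_allele(.data$alt) == .data$ref_ref ~ 4L,
        TRUE ~ NA_integer_
      )
    ) |>
    dplyr::filter(!is.na(.data$match_type)) |>
    dplyr::group_by(.data$.row) |>
    dplyr::slice_min(.data$match_type, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      ref_alt = ifelse(.data$match_type %in% c(2L, 4L),
                       .data$an - .data$ac, .data$ac),
      ref_total = .data$an
    )
  ambiguous <- study$ref == complement_allele(study$alt)
  matched_rows <- study$.row %in% cand$.row
  site_rows <- study$.row %in%
    study$.row[paste(study$chrom_key, study$pos) %in%
                 paste(ref$chrom_key, ref$pos_key)]
  reason <- dplyr::case_when(
    ambiguous ~ "strand_ambiguous",
    !site_rows ~ "unmatched_site",
    !matched_rows ~ "allele_mismatch",
    TRUE ~ NA_character_
  )
  keep <- is.na(reason)
  out <- study |>
    dplyr::filter(keep) |>
    dplyr::left_join(cand |> dplyr::select(".row", "ref_alt", "ref_total"),
                     by = ".row") |>
    dplyr::select(-".row", -"chrom_key")
  drop_log <- study |>
    dplyr::filter(!keep) |>
    dplyr::mutate(reason = reason[!keep]) |>
    dplyr::select("chrom", "pos", dplyr::any_of("rsid"), "reason")
  if (nrow(study) > 0 && mean(site_rows) < 0.5) {
    warning("fewer than 50% of study sites found in the reference; ",
            "check that study and reference share a genome build")
  }
  attr(out, "drop_log") <- drop_log
  out
}

norm_chrom <- function(x) sub("^chr", "", as.character(x))

complement_allele <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

#' Filter SNPs by the exact Hardy-Weinberg test
#'
#' Removes SNPs whose exact HWE p-value falls below `threshold` (0.001 by
#' default). By default the test uses the control genotype counts — the
#' standard GWAS practice, since HWE departures in cases can be genuine
#' disease signal and the reference panel carries no genotypes —
#' or case and control jointly with `population = "both"`.
#'
#' @param snps SNP tibble with genotype-count columns
#'   `control_hom_ref`, `control_het`, `control_hom_alt` (and the `case_*`
#'   equivalents for `population = "both"`).
#' @param threshold Removal threshold on the exact HWE p-value.
#' @param population Genotypes to test: `"control"` (default) or `"both"`.
#' @return A list with tibbles `kept` and `removed`; both gain an `hwe_p`
#'   column, and `removed` a `reason` column.
#' @export
hwe_filter <- function(snps, threshold = 0.001,
                       population = c("control", "both")) {
  population <- match.arg(population)
  cols <- c("control_hom_ref", "control_het", "control_hom_alt")
  if (population == "both") {
    cols <- c(cols, "case_hom_ref", "case_het", "case_hom_alt")
  }
  missing_cols <- setdiff(cols, names(snps))
  if (length(missing_cols) > 0) {
    stop("missing genotype columns: ", paste(missing_cols, collapse = ", "))
  }
  hom_ref <- snps$control_hom_ref
  het <- snps$control_het
  hom_alt <- snps$control_hom_alt
  if (population == "both") {
    hom_ref <- hom_ref + snps$case_hom_ref
    het <- het + snps$case_het
    hom_alt <- hom_alt + snps$case_hom_alt
  }
  p <- hwe_exact_test(hom_ref, het, hom_alt)
  out <- dplyr::mutate(tibble::as_tibble(snps), hwe_p = p)
  list(
    kept = dplyr::filter(out, .data$hwe_p >= threshold),
    removed = out |>
      dplyr::filter(.data$hwe_p < threshold) |>
      dplyr::mutate(reason = sprintf("hwe_p=%.3g < %g", .data$hwe_p,
                                     threshold))
  )
}

#' Bonferroni family-wise significance threshold
#'
#' @param m Number of tests (SNPs surviving QC).
#' @param family_alpha Family-wise error rate; default 0.05.
#' @return `family_alpha / m`.
#' @examples
#' bonferroni_threshold(416667)   # ~1.2e-7
#' bonferroni_threshold(700280)   # ~7.14e-8
#' @export
bonferroni_threshold <- function(m, family_alpha = 0.05) {
  if (length(m) != 1 || is.na(m) || m < 1) {
    stop("m must be a positive number of tests")
  }
  family_alpha / m
}

#' Genome-wide reference-powered association analysis
#'
#' Runs [rrpat_test()] on every SNP (reference already joined and
#' HWE-filtered), flags significance of `P(ca-co)` and `P(T)` at the
#' Bonferroni threshold, classifies each SNP, and computes the genomic
#' inflation factor of both p-value sets. Classes:
#' \describe{
#'   \item{`positive_both`}{significant by both the plain case-control test
#'     and `P(T)`.}
#'   \item{`rescued`}{non-significant by the plain test but significant by
#'     `P(T)`, with the reference-compatibility gate passed — the variants
#'     the reference panel recovers.}
#'   \item{`lost`}{significant by the plain test only.}
#'   \item{`negative`}{neither significant; also any SNP whose only
#'     significant result is a gate-failed `P(T)`, which is not trusted.}
#' }
#'
#' @param snps SNP tibble with the six count columns of [rrpat_test()].
#' @param gate Reference-compatibility threshold on `P(co-re)`.
#' @param threshold Per-test significance threshold. Defaults to
#'   `bonferroni_threshold(m, family_alpha)` with `m = nrow(snps)`; pass a
#'   published threshold directly to reproduce a specific analysis.
#' @param m,family_alpha Used to derive `threshold` when it is not given.
#' @param gate_action `"flag"` (default) keeps gate-failing SNPs in the
#'   output with `reference_compatible = FALSE`; `"filter"` removes them.
#' @param top Optional: keep only the `top` SNPs with the smallest
#'   `P(ca-co)` for classification (the "first N lowest p-values" follow-up
#'   selection); `Inf` (default) keeps all.
#' @return An object of class `rrpat_result`: a list with `snps` (per-SNP
#'   results incl. `sig_ca_co`, `sig_t`, `rescue_class`), `lambda`
#'   (genomic inflation of `p_t` and `p_ca_co`), `threshold`, `gate` and
#'   counts. Supports [tidy()], [glance()], [autoplot()] and `print()`.
#' @export
run_rrpat <- function(snps, gate = 0.01, threshold = NULL, m = NULL,
                      family_alpha = 0.05,
                      gate_action = c("flag", "filter"), top = Inf) {
  gate_action <- match.arg(gate_action)
  if (nrow(snps) == 0) stop("no SNPs to test")
  if (is.null(threshold)) {
    threshold <- bonferroni_threshold(if (is.null(m)) nrow(snps) else m,
                                      family_alpha)
  }
  res <- rrpat_test(snps, gate = gate)
  if (is.finite(top) && top < nrow(res)) {
    res <- res |> dplyr::arrange(.data$p_ca_co) |> head(top)
  }
  res <- res |>
    dplyr::mutate(
      sig_ca_co = .data$p_ca_co < threshold,
      sig_t = .data$p_t < threshold,
      rescue_class = dplyr::case_when(
        .data$sig_ca_co & .data$sig_t ~ "positive_both",
        !.data$sig_ca_co & .data$sig_t & .data$reference_compatible ~
          "rescued",
        .data$sig_ca_co & !.data$sig_t ~ "lost",
        TRUE ~ "negative"
      )
    )
  if (gate_action == "filter") {
    res <- dplyr::filter(res, .data$reference_compatible)
  }
  lambda <- tibble::tibble(
    test = c("t", "ca_co"),
    lambda = c(genomic_inflation(res$p_t),
               genomic_inflation(res$p_ca_co))
  )
  structure(
    list(snps = res, lambda = lambda, threshold = threshold, gate = gate,
         n_snps = nrow(res)),
    class = "rrpat_result"
  )
}

#' Genomic inflation factor (lambda)
#'
#' Median-based lambda: each p-value is transformed to a 1-df chi-square
#' quantile, and the median of these is divided by the null median
#' `qchisq(0.5, 1) = 0.4549`. Lambda near 1 indicates a well-calibrated
#' test; values above 1 indicate inflation, e.g. from population
#' stratification.
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @return Positive scalar.
#' @export
genomic_inflation <- function(pvalues) {
  if (length(pvalues) == 0) stop("empty p-value list")
  check_pvalue(pvalues)
  median(qchisq(pvalues, df = 1, lower.tail = FALSE)) / qchisq(0.5, df = 1)
}

#' Export Manhattan and QQ plotting tables
#'
#' @param result An `rrpat_result` from [run_rrpat()].
#' @return A list with two tibbles: `manhattan` (chrom, pos, rsid and
#'   `-log10` of both `P(T)` and `P(ca-co)`) and `qq` (sorted observed
#'   `-log10` p-values of both tests against expected quantiles
#'   `-log10((i - 0.5)/n)`).
#' @export
manhattan_qq_export <- function(result) {
  stopifnot(inherits(result, "rrpat_result"))
  snps <- result$snps
  if (nrow(snps) == 0) stop("empty result")
  manhattan <- snps |>
    dplyr::select(dplyr::any_of(c("chrom", "pos", "rsid")),
                  neg_log10_p_t = "neg_log10_p_t") |>
    dplyr::mutate(neg_log10_p_ca_co = -log10(snps$p_ca_co))
  n <- nrow(snps)
  qq <- tibble::tibble(
    expected = -log10((seq_len(n) - 0.5) / n),
    observed_t = sort(snps$neg_log10_p_t, decreasing = TRUE),
    observed_ca_co = sort(-log10(snps$p_ca_co), decreasing = TRUE)
  )
  list(manhattan = manhattan, qq = qq)
}

#' @export
print.rrpat_result <- function(x, ...) {
  cls <- table(x$snps$rescue_class)
  cat("Reference-powered association result\n")
  cat(sprintf("  SNPs tested:        %d\n", x$n_snps))
  cat(sprintf("  threshold:          %.3g, gate: %g\n", x$threshold, x$gate))
  cat(sprintf("  lambda P(T):        %.3f\n",
              x$lambda$lambda[x$lambda$test == "t"]))
  cat(sprintf("  lambda P(ca-co):    %.3f\n",
              x$lambda$lambda[x$lambda$test == "ca_co"]))
  for (k in c("positive_both", "rescued", "lost", "negative")) {
    cat(sprintf("  %-14s %d\n", paste0(k, ":"),
                if (k %in% names(cls)) cls[[k]] else 0L))
  }
  invisible(x)
}

#' @rdname run_rrpat
#' @param x An `rrpat_result`.
#' @param ... Unused.
#' @method tidy rrpat_result
#' @export
tidy.rrpat_result <- function(x, ...) {
  x$snps
}

#' @rdname run_rrpat
#' @method glance rrpat_result
#' @export
glance.rrpat_result <- function(x, ...) {
  cls <- x$snps$rescue_class
  tibble::tibble(
    n_snps = x$n_snps,
    threshold = x$threshold,
    gate = x$gate,
    lambda_t = x$lambda$lambda[x$lambda$test == "t"],
    lambda_ca_co = x$lambda$lambda[x$lambda$test == "ca_co"],
    n_positive_both = sum(cls == "positive_both"),
    n_rescued = sum(cls == "rescued"),
    n_lost = sum(cls == "lost")
  )
}
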