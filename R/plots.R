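#' Manhattan plot of a pipeline result
#'
#' Two stacked panels compare `-log10 P(ca-co)` (plain case-control test)
#' with `-log10 P(T)` (reference-powered test) along the genome; the dashed
#' line marks the per-test significance threshold.
#'
#' @param result An `rrpat_result` from [run_rrpat()].
#' @return A ggplot object.
#' @export
plot_manhattan <- function(result) {
  stopifnot(inherits(result, "rrpat_result"))
  exp_ <- manhattan_qq_export(result)
  df <- exp_$manhattan |>
    dplyr::mutate(chrom = factor(norm_chrom(.data$chrom),
                                 levels = unique(norm_chrom(.data$chrom))),
                  x = dplyr::row_number()) |>
    tidyr::pivot_longer(c("neg_log10_p_t", "neg_log10_p_ca_co"),
                        names_to = "test", values_to = "neg_log10_p") |>
    dplyr::mutate(test = dplyr::recode(.data$test,
                                       neg_log10_p_t = "P(T)",
                                       neg_log10_p_ca_co = "P(ca-co)"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$neg_log10_p,
                                   colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(result$threshold),
                        linetype = "dashed") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$test)) +
    ggplot2::labs(x = "SNP (genome order)",
                  y = expression(-log[10](italic(p)))) +
    ggplot2::theme_minimal()
}

#' QQ plot of a pipeline result
#'
#' Observed versus expected `-log10` p-value quantiles for both the
#' reference-powered and the plain case-control test.
#'
#' @inheritParams plot_manhattan
#' @return A ggplot object.
#' @export
plot_qq <- function(result) {
  stopifnot(inherits(result, "rrpat_result"))
  qq <- manhattan_qq_export(result)$qq |>
    tidyr::pivot_longer(c("observed_t", "observed_ca_co"),
                        names_to = "test", values_to = "observed") |>
    dplyr::mutate(test = dplyr::recode(.data$test,
                                       observed_t = "P(T)",
                                       observed_ca_co = "P(ca-co)"))
  ggplot2::ggplot(qq, ggplot2::aes(x = .data$expected, y = .data$observed,
                                   colour = .data$test)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(size = 0.7) +
    ggplot2::labs(x = expression(Expected ~ -log[10](italic(p))),
                  y = expression(Observed ~ -log[10](italic(p))),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_manhattan
#' @param object An `rrpat_result`.
#' @param type `"manhattan"` or `"qq"`.
#' @param ... Unused.
#' @method autoplot rrpat_result
#' @export
autoplot.rrpat_result <- function(object, type = c("manhattan", "qq"), ...) {
  type <- match.arg(type)
  if (type == "manhattan") plot_manhattan(object) else plot_qq(object)
}

#' Plot simulated rejection rates
#'
#' Dot plot of the empirical rejection proportions of the four tests from
#' [run_scenario()]/[run_scenarios()], one panel per significance level,
#' with +/- 3 Monte-Carlo standard-error bars and the nominal level marked.
#'
#' @param results Long results tibble from [run_scenario()].
#' @return A ggplot object.
#' @export
plot_rejection_rates <- function(results) {
  df <- results |>
    dplyr::mutate(
      scenario = sprintf("n=%d/%d/%d\nq=%.3g/%.3g/%.3g",
                         .data$n_case, .data$n_control, .data$n_ref,
                         .data$q_case, .data$q_control, .data$q_ref)
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$test, y = .data$reject_rate,
                                   colour = .data$scenario)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(0, .data$reject_rate - 3 * .data$mc_se),
                   ymax = pmin(1, .data$reject_rate + 3 * .data$mc_se)),
      width = 0.2, position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$alpha),
                        linetype = "dotted") +
    ggplot2::facet_wrap(ggplot2::vars(.data$alpha), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "rejection rate", colour = NULL) +
    ggplot2::theme_minimal()
}
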