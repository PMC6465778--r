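#' Build a simulation scenario
#'
#' One cell of the Monte-Carlo study: three group sizes (individuals), three
#' allele frequencies, a replicate count and a seed. Under each replicate the
#' alt-allele count of each group is drawn Binomial(2N, q) and the full test
#' battery is applied to the three counts.
#'
#' @param n_case,n_control,n_ref Group sizes in individuals (chromosome
#'   counts are 2N).
#' @param q_case,q_control,q_ref Alt-allele frequencies, strictly inside
#'   (0, 1).
#' @param n_reps Number of Monte-Carlo replicates.
#' @param seed Integer seed for the scenario's private RNG stream.
#' @return A one-row tibble with the scenario parameters.
#' @examples
#' sim_scenario(500, 500, 10000, 0.15, 0.15, 0.15, n_reps = 1000)
#' @export
sim_scenario <- function(n_case, n_control, n_ref,
                         q_case, q_control, q_ref,
                         n_reps = 100000, seed = 1L) {
  stopifnot(n_case >= 1, n_control >= 1, n_ref >= 1, n_reps >= 1)
  for (q in c(q_case, q_control, q_ref)) {
    if (is.na(q) || q <= 0 || q >= 1) {
      stop("allele frequencies must lie strictly inside (0, 1)")
    }
  }
  tibble::tibble(
    n_case = as.integer(n_case), n_control = as.integer(n_control),
    n_ref = as.integer(n_ref),
    q_case = q_case, q_control = q_control, q_ref = q_ref,
    n_reps = as.integer(n_reps), seed = as.integer(seed)
  )
}

#' Draw binomial allele counts for one group
#'
#' Samples the alt-allele count of a group of `n` diploid individuals with
#' allele frequency `q` as Binomial(2n, q), the sampling model of the
#' Monte-Carlo study.
#'
#' @param n Group size in individuals.
#' @param q Alt-allele frequency in (0, 1).
#' @param n_draws Number of independent draws.
#' @return A tibble with columns `alt_count` and `chrom_total` (= 2n).
#' @examples
#' withr::with_seed(1, draw_allele_count(10000, 0.15, n_draws = 5))
#' @export
draw_allele_count <- function(n, q, n_draws = 1) {
  stopifnot(n >= 1, n_draws >= 1)
  if (is.na(q) || q <= 0 || q >= 1) {
    stop("allele frequency must lie strictly inside (0, 1)")
  }
  tibble::tibble(alt_count = rbinom(n_draws, 2 * n, q),
                 chrom_total = rep(2L * as.integer(n), n_draws))
}

#' Run one Monte-Carlo scenario
#'
#' Draws `n_reps` independent triples of binomial allele counts (case,
#' control, reference), computes the four p-values per replicate —
#' case vs control+reference, control vs reference, case vs control, and the
#' reference-powered `P(T)` — and tallies empirical rejection proportions at
#' each significance level. Replicates where all groups are monomorphic give
#' all Fisher p-values 1 and `P(T) = 0.5`; they count as non-rejections and
#' are never dropped (dropping them would bias the type-I error).
#'
#' The scenario's `seed` drives a private RNG stream via [withr::with_seed()],
#' so the same scenario always returns a bitwise-identical result and does
#' not disturb the caller's RNG state.
#'
#' @param scenario A one-row data frame as returned by [sim_scenario()].
#' @param alphas Significance levels to tally.
#' @param strict Reject when `p < alpha` (default); `FALSE` uses `p <= alpha`.
#' @return A tibble in long form: the scenario columns plus `alpha`, `test`
#'   (one of `"ca_core"`, `"co_re"`, `"ca_co"`, `"t"`), `rejections`,
#'   `reject_rate` and the Monte-Carlo standard error
#'   `mc_se = sqrt(r(1-r)/n_reps)`.
#' @examples
#' s <- sim_scenario(100, 100, 1000, 0.2, 0.2, 0.2, n_reps = 500, seed = 7)
#' run_scenario(s)
#' @export
run_scenario <- function(scenario, alphas = c(0.05, 0.01, 0.001),
                         strict = TRUE) {
  stopifnot(is.data.frame(scenario), nrow(scenario) == 1)
  s <- as.list(scenario)
  pv <- withr::with_seed(s$seed, scenario_pvalues(s))
  tests <- c("ca_core", "co_re", "ca_co", "t")
  res <- tidyr::expand_grid(alpha = alphas, test = tests) |>
    dplyr::mutate(
      rejections = purrr::map2_int(.data$alpha, .data$test, function(a, tst) {
        p <- pv[[tst]]
        if (strict) sum(p < a) else sum(p <= a)
      }),
      reject_rate = .data$rejections / s$n_reps,
      mc_se = sqrt(.data$reject_rate * (1 - .data$reject_rate) / s$n_reps)
    )
  dplyr::bind_cols(scenario[rep(1, nrow(res)), , drop = FALSE], res)
}

# the four p-value vectors for one scenario (expects RNG already seeded)
scenario_pvalues <- function(s) {
  ca <- rbinom(s$n_reps, 2 * s$n_case, s$q_case)
  co <- rbinom(s$n_reps, 2 * s$n_control, s$q_control)
  re <- rbinom(s$n_reps, 2 * s$n_ref, s$q_ref)
  m_case <- 2 * s$n_case
  m_control <- 2 * s$n_control
  m_ref <- 2 * s$n_ref
  lp1 <- fisher_log_p_margins(ca, ca + co + re, m_case, m_control + m_ref)
  lp2 <- fisher_log_p_margins(co, co + re, m_control, m_ref)
  lp3 <- fisher_log_p_margins(ca, ca + co, m_case, m_control)
  list(ca_core = exp(lp1), co_re = exp(lp2), ca_co = exp(lp3),
       t = p_of_t_log(lp1, lp2))
}

#' Run a table of scenarios
#'
#' Maps [run_scenario()] over the rows of a scenario table (e.g. from
#' [build_grid()] or [read_scenarios()]) and binds the long results.
#'
#' @param scenarios A data frame of scenarios, one per row.
#' @inheritParams run_scenario
#' @return A long tibble of rejection rates; see [run_scenario()].
#' @export
run_scenarios <- function(scenarios, alphas = c(0.05, 0.01, 0.001),
                          strict = TRUE) {
  purrr::map(seq_len(nrow(scenarios)), function(i) {
    run_scenario(scenarios[i, , drop = FALSE], alphas = alphas,
                 strict = strict)
  }) |> purrr::list_rbind()
}

#' The full factorial simulation grid
#'
#' The Cartesian grid of the Monte-Carlo study: case sizes 100/500/1000/3000;
#' control sizes 0.5x, 1x, 2x and 5x the case size; reference sizes 10,000
#' and 100,000; reference allele frequencies 0.001/0.01/0.05/0.15/0.3;
#' control frequencies 1x and 1.1x the reference frequency; case frequencies
#' 1x, 1.1x, 1.5x and 3x the reference frequency. This yields
#' 4 x 4 x 2 x 5 x 2 x 4 = 1,280 parameter cells; each cell is simulated with
#' `n_reps` replicates. Every case frequency in the grid stays below 1 (the
#' largest is 3 x 0.3 = 0.9).
#'
#' @param n_reps Replicates per cell.
#' @param seed Master seed; each cell receives its own derived stream seed,
#'   so any subset of the grid reproduces identically.
#' @return A tibble of 1,280 scenarios with a `scenario_id` column.
#' @export
build_grid <- function(n_reps = 100000, seed = 1L) {
  g <- tidyr::expand_grid(
    n_case = c(100L, 500L, 1000L, 3000L),
    control_mult = c(0.5, 1, 2, 5),
    n_ref = c(10000L, 100000L),
    q_ref = c(0.001, 0.01, 0.05, 0.15, 0.3),
    control_freq_mult = c(1, 1.1),
    case_freq_mult = c(1, 1.1, 1.5, 3)
  )
  g |>
    dplyr::mutate(
      scenario_id = dplyr::row_number(),
      n_control = as.integer(.data$n_case * .data$control_mult),
      q_control = .data$q_ref * .data$control_freq_mult,
      q_case = .data$q_ref * .data$case_freq_mult,
      n_reps = as.integer(n_reps),
      seed = derive_seed(seed, .data$scenario_id)
    ) |>
    dplyr::select("scenario_id", "n_case", "n_control", "n_ref",
                  "q_case", "q_control", "q_ref", "n_reps", "seed")
}

# deterministic per-index stream seed below 2^31
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) %% 2147483629 * 69069 + index) %% 2147483629)
}

#' Null-calibration QQ data for P(T)
#'
#' Simulates a scenario and pairs the sorted observed `P(T)` values with
#' uniform order-statistic expectations `(i - 0.5)/n`, for a QQ plot
#' assessing calibration of the statistic under the null. The scenario should
#' have all three frequencies equal (H0); a warning is emitted otherwise and
#' the data are still returned.
#'
#' Because Fisher p-values are discrete, observed `P(T)` is conservative:
#' in the tail the observed p-values sit at or above the expected diagonal.
#'
#' @inheritParams run_scenario
#' @return A tibble with columns `expected` and `observed` (p-value scale,
#'   sorted ascending) plus their `-log10` transforms.
#' @export
null_qq_data <- function(scenario) {
  stopifnot(is.data.frame(scenario), nrow(scenario) == 1)
  s <- as.list(scenario)
  if (length(unique(c(s$q_case, s$q_control, s$q_ref))) != 1) {
    warning("scenario is not under H0: allele frequencies differ across groups")
  }
  pv <- withr::with_seed(s$seed, scenario_pvalues(s))
  obs <- sort(pv$t)
  n <- length(obs)
  tibble::tibble(
    expected = (seq_len(n) - 0.5) / n,
    observed = obs,
    neg_log10_expected = -log10((seq_len(n) - 0.5) / n),
    neg_log10_observed = -log10(obs)
  )
}

#' Read a scenario table
#'
#' Reads a TSV of scenarios, one per row, with columns `n_case`, `q_case`,
#' `n_control`, `q_control`, `n_ref`, `q_ref`, `n_reps`, `seed`. Malformed
#' rows (wrong field count, non-numeric values) abort with the offending
#' line.
#'
#' @param path Path to the scenario TSV.
#' @return A tibble of scenarios.
#' @export
read_scenarios <- function(path) {
  df <- read_tsv_strict(path,
                        c("n_case", "q_case", "n_control", "q_control",
                          "n_ref", "q_ref", "n_reps", "seed"))
  purrr::pmap(df, sim_scenario) |> purrr::list_rbind()
}

#' Write simulation results as a wide TSV
#'
#' Pivots the long output of [run_scenario()]/[run_scenarios()] into one row
#' per scenario x alpha with one rejection-rate column per test
#' (`ca_core`, `co_re`, `ca_co`, `t`) and matching Monte-Carlo standard-error
#' columns (`*_se`).
#'
#' @param results Long results tibble.
#' @param path Output TSV path.
#' @return The wide tibble, invisibly.
#' @export
write_sim_results <- function(results, path) {
  wide <- results |>
    dplyr::select(-"rejections") |>
    tidyr::pivot_wider(names_from = "test",
                       values_from = c("reject_rate", "mc_se"),
                       names_glue = "{test}{ifelse(.value == 'mc_se', '_se', '')}")
  readr::write_tsv(wide, path)
  invisible(wide)
}
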