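test_that("binomial allele draws have the right moments and bounds", {
  d <- withr::with_seed(5, draw_allele_count(10000, 0.15, n_draws = 1e5))
  expect_true(all(d$chrom_total == 20000))
  expect_true(all(d$alt_count >= 0 & d$alt_count <= 20000))
  mc_se <- sqrt(20000 * 0.15 * 0.85 / 1e5)
  expect_lt(abs(mean(d$alt_count) - 3000), 3 * mc_se)
  expect_lt(abs(var(d$alt_count) / (20000 * 0.15 * 0.85) - 1), 0.02)
  expect_identical(withr::with_seed(5, draw_allele_count(100, 0.3, 10)),
                   withr::with_seed(5, draw_allele_count(100, 0.3, 10)))
  expect_error(draw_allele_count(100, 0), "strictly inside")
  expect_error(draw_allele_count(100, 1), "strictly inside")
})

test_that("scenario construction validates frequencies and sizes", {
  expect_error(sim_scenario(100, 100, 100, 0.5, 1, 0.5), "strictly inside")
  expect_error(sim_scenario(100, 100, 100, 0, 0.5, 0.5), "strictly inside")
  s <- sim_scenario(500, 250, 10000, 0.1, 0.1, 0.1, n_reps = 10, seed = 3)
  expect_equal(s$n_control, 250L)
  expect_equal(s$n_reps, 10L)
})

test_that("identical seeds give bitwise-identical scenario results", {
  s <- sim_scenario(200, 200, 2000, 0.2, 0.2, 0.2, n_reps = 2000, seed = 77)
  expect_identical(run_scenario(s), run_scenario(s))
  s2 <- sim_scenario(200, 200, 2000, 0.2, 0.2, 0.2, n_reps = 2000, seed = 78)
  expect_false(identical(run_scenario(s), run_scenario(s2)))
})

test_that("rejection rates are monotone non-increasing in alpha", {
  s <- sim_scenario(300, 300, 3000, 0.18, 0.165, 0.15, n_reps = 3000,
                    seed = 21)
  r <- run_scenario(s, alphas = c(0.1, 0.05, 0.01, 0.001))
  rates <- r |>
    dplyr::arrange(dplyr::desc(alpha)) |>
    dplyr::group_by(test) |>
    dplyr::summarise(mono = all(diff(reject_rate) <= 0))
  expect_true(all(rates$mono))
})

test_that("under the exact null every test is conservative at each alpha", {
  s <- sim_scenario(250, 250, 5000, 0.15, 0.15, 0.15, n_reps = 8000,
                    seed = 41)
  r <- run_scenario(s)
  # Fisher discreteness makes all four tests conservative; allow 3 MC SE
  bound <- r$alpha + 3 * sqrt(r$alpha * (1 - r$alpha) / s$n_reps)
  expect_true(all(r$reject_rate <= bound))
})

test_that("power of T grows with case sample size", {
  rates <- vapply(c(100, 300, 900), function(n) {
    s <- sim_scenario(n, n, 10000, 0.20, 0.15, 0.15, n_reps = 2000,
                      seed = 600 + n)
    r <- run_scenario(s, alphas = 0.05)
    r$reject_rate[r$test == "t"]
  }, numeric(1))
  expect_true(all(diff(rates) > 0))
})

test_that("T controls drift false positives better than naive pooling", {
  # control-reference drift: q_case = q_control = 1.1 * q_ref
  fp <- lapply(c(1, 5), function(mult) {
    s <- sim_scenario(500, 500 * mult, 10000, 0.165, 0.165, 0.15,
                      n_reps = 4000, seed = 900 + mult)
    r <- run_scenario(s, alphas = 0.05)
    list(t = r$reject_rate[r$test == "t"],
         naive = r$reject_rate[r$test == "ca_core"])
  })
  # T below the naive merged test at both control sizes
  expect_lt(fp[[1]]$t, fp[[1]]$naive)
  expect_lt(fp[[2]]$t, fp[[2]]$naive)
  # and the protection widens as controls outnumber cases
  expect_lt(fp[[2]]$t, fp[[1]]$t)
  expect_gt(fp[[2]]$naive - fp[[2]]$t, fp[[1]]$naive - fp[[1]]$t)
})

test_that("monomorphic replicates count as non-rejections", {
  # q so small that many replicates draw zero alt alleles everywhere
  s <- sim_scenario(20, 20, 50, 0.002, 0.002, 0.002, n_reps = 500, seed = 8)
  r <- run_scenario(s, alphas = c(0.05, 1))
  expect_true(all(r$reject_rate[r$alpha == 0.05] < 0.05))
  # at alpha = 1 every replicate rejects under the strict rule iff p < 1;
  # monomorphic draws have p = 1 for the Fisher tests, so rates stay below 1
  expect_true(all(r$reject_rate[r$alpha == 1 & r$test != "t"] < 1))
})

test_that("the factorial grid has the documented structure", {
  g <- build_grid(n_reps = 10, seed = 4)
  expect_equal(nrow(g), 1280L)
  expect_equal(length(unique(g$seed)), 1280L)
  # stated corners
  expect_true(any(g$n_case == 100 & g$n_control == 50 & g$n_ref == 10000 &
                    g$q_ref == 0.001 & g$q_control == 0.001 &
                    g$q_case == 0.003))
  expect_true(any(g$n_case == 3000 & g$n_control == 15000 &
                    g$n_ref == 100000 & g$q_ref == 0.3 &
                    abs(g$q_control - 0.33) < 1e-12 &
                    abs(g$q_case - 0.9) < 1e-12))
  # every case frequency stays inside (0, 1)
  expect_true(all(g$q_case > 0 & g$q_case < 1))
  # level counts multiply out: 4 * 4 * 2 * 5 * 2 * 4
  expect_equal(length(unique(g$n_case)), 4L)
  expect_equal(length(unique(g$n_ref)), 2L)
  expect_equal(length(unique(g$q_ref)), 5L)
})

test_that("null QQ data pair sorted P(T) with uniform expectations", {
  s <- sim_scenario(100, 100, 1000, 0.2, 0.2, 0.2, n_reps = 400, seed = 15)
  qq <- null_qq_data(s)
  expect_equal(nrow(qq), 400L)
  expect_true(!is.unsorted(qq$observed))
  expect_equal(qq$expected, (seq_len(400) - 0.5) / 400)
  # discreteness-induced conservativeness: the smallest observed P(T) should
  # not undershoot the uniform expectation by much
  expect_gt(qq$observed[1], qq$expected[1] / 10)
  s1 <- sim_scenario(50, 50, 500, 0.2, 0.2, 0.2, n_reps = 1, seed = 2)
  expect_equal(null_qq_data(s1)$expected, 0.5)
  s_h1 <- sim_scenario(100, 100, 1000, 0.3, 0.2, 0.2, n_reps = 10, seed = 3)
  expect_warning(qq_h1 <- null_qq_data(s_h1), "not under H0")
  expect_equal(nrow(qq_h1), 10L)
})

test_that("scenario tables round-trip through TSV and results pivot wide", {
  dir <- withr::local_tempdir()
  scn <- dplyr::bind_rows(
    sim_scenario(100, 100, 1000, 0.2, 0.2, 0.2, n_reps = 200, seed = 1),
    sim_scenario(100, 200, 1000, 0.22, 0.2, 0.2, n_reps = 200, seed = 2)
  )
  f <- file.path(dir, "scenarios.tsv")
  readr::write_tsv(scn, f)
  expect_equal(read_scenarios(f), scn)
  res <- run_scenarios(scn, alphas = c(0.05, 0.01))
  expect_equal(nrow(res), 2 * 2 * 4)
  out <- file.path(dir, "sim.tsv")
  wide <- write_sim_results(res, out)
  expect_equal(nrow(wide), 4L)   # scenario x alpha
  expect_true(all(c("ca_core", "co_re", "ca_co", "t", "t_se") %in%
                    names(wide)))
  expect_true(file.exists(out))
})
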