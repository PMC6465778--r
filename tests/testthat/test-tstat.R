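test_that("T is the difference of the component log p-values", {
  expect_equal(t_statistic(0.01, 0.01), 0)
  expect_equal(t_statistic(exp(-5), exp(-2)), -3)
  expect_equal(t_statistic(1, 1), 0)
  expect_equal(t_statistic(0.2, 0.05), log(0.2) - log(0.05))
})

test_that("invalid p-values are rejected", {
  expect_error(t_statistic(0, 0.5), "invalid p-value")
  expect_error(t_statistic(0.5, 1.2), "invalid p-value")
  expect_error(p_of_t(-1, 0.5), "invalid p-value")
  expect_error(p_of_t(0.5, 0), "invalid p-value")
})

test_that("P(T) matches its closed form on both branches", {
  expect_equal(p_of_t(0.01, 0.5), 0.01)       # p1/(2 p2)
  expect_equal(p_of_t(0.5, 0.01), 0.99)       # 1 - p2/(2 p1)
  for (p in c(1e-6, 0.001, 0.05, 0.3, 0.99, 1)) {
    expect_equal(p_of_t(p, p), 0.5)           # branch boundary
  }
})

test_that("the two branches meet continuously at p1 = p2", {
  for (p in seq(0.05, 0.95, by = 0.1)) {
    for (eps in c(1e-6, 1e-9, 1e-12)) {
      expect_lt(abs(p_of_t(p, p + eps) - 0.5), 2 * eps / p + 1e-12)
      expect_lt(abs(p_of_t(p + eps, p) - 0.5), 2 * eps / p + 1e-12)
    }
  }
})

test_that("P(T) is monotone: increasing in p1, decreasing in p2", {
  grid <- seq(0.005, 0.995, length.out = 50)
  for (p2 in c(0.01, 0.2, 0.7)) {
    vals <- p_of_t(grid, rep(p2, length(grid)))
    expect_true(all(diff(vals) > 0))
  }
  for (p1 in c(0.01, 0.2, 0.7)) {
    vals <- p_of_t(rep(p1, length(grid)), grid)
    expect_true(all(diff(vals) < 0))
  }
})

test_that("under continuous-uniform nulls T is Laplace(0,1) and P(T) uniform", {
  withr::with_seed(2026, {
    u1 <- runif(1e5)
    u2 <- runif(1e5)
  })
  tv <- t_statistic(u1, u2)
  ks_l <- suppressWarnings(stats::ks.test(tv, laplace_cdf))
  expect_lt(unname(ks_l$statistic), 0.01)
  pt <- p_of_t(u1, u2)
  ks_u <- suppressWarnings(stats::ks.test(pt, "punif"))
  expect_lt(unname(ks_u$statistic), 0.01)
  # and P(T) is exactly the Laplace lower-tail probability of T
  expect_equal(pt[1:1000], laplace_cdf(tv[1:1000]), tolerance = 1e-12)
})

test_that("merge_counts pools counts componentwise and commutes", {
  m <- merge_counts(10, 1000, 100, 20000)
  expect_equal(m$alt_count, 110)
  expect_equal(m$chrom_total, 21000)
  expect_equal(merge_counts(0, 10, 0, 10)$alt_count, 0)
  expect_identical(merge_counts(3, 8, 5, 12), merge_counts(5, 12, 3, 8))
})

test_that("rrpat_test output is internally consistent", {
  snps <- tibble::tibble(
    case_alt = 30, case_total = 200, control_alt = 15, control_total = 200,
    ref_alt = 750, ref_total = 10000
  )
  r <- rrpat_test(snps)
  expect_equal(r$t_value, log(r$p_ca_core) - log(r$p_co_re))
  expect_equal(r$p_t, p_of_t(r$p_ca_core, r$p_co_re))
  # the pooled comparison group is control + reference
  expect_equal(r$p_ca_core,
               fisher_exact_2x2(30, 200, 15 + 750, 200 + 10000))
  expect_equal(r$p_ca_co, fisher_exact_2x2(30, 200, 15, 200))
  expect_true(r$reference_compatible)
})

test_that("near-identical groups give all p-values near 1 and P(T) near 1/2", {
  snps <- tibble::tibble(
    case_alt = 1500, case_total = 10000, control_alt = 1500,
    control_total = 10000, ref_alt = 1500, ref_total = 10000
  )
  r <- rrpat_test(snps)
  expect_gt(r$p_ca_core, 0.9)
  expect_gt(r$p_co_re, 0.9)
  expect_lt(abs(r$p_t - 0.5), 0.05)
})

test_that("strong control-reference differentiation fails the gate", {
  snps <- tibble::tibble(
    case_alt = 200, case_total = 1000, control_alt = 400,
    control_total = 1000, ref_alt = 1500, ref_total = 10000
  )
  r <- rrpat_test(snps)
  expect_lt(r$p_co_re, 0.01)
  expect_false(r$reference_compatible)
})

test_that("neg_log10_p_t stays exact where p_t underflows", {
  # p1 ~ exp(-800), p2 = 0.5: p_t = p1/(2 p2) underflows double precision
  snps <- tibble::tibble(
    case_alt = 900, case_total = 1000, control_alt = 150,
    control_total = 1000, ref_alt = 3000, ref_total = 20000
  )
  r <- rrpat_test(snps)
  expect_true(is.finite(r$neg_log10_p_t))
  expect_gt(r$neg_log10_p_t, 100)
  # consistent with the log-scale component p-values
  lp1 <- fisher_exact_2x2(900, 1000, 3150, 21000, log.p = TRUE)
  lp2 <- fisher_exact_2x2(150, 1000, 3000, 20000, log.p = TRUE)
  expect_equal(r$neg_log10_p_t, -(lp1 - log(2) - lp2) / log(10),
               tolerance = 1e-10)
})

test_that("rrpat_test validates its input table", {
  expect_error(rrpat_test(tibble::tibble(case_alt = 1)), "missing count")
  snps <- toy_snps(3)
  expect_error(rrpat_test(snps, gate = 0), "invalid p-value")
})
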