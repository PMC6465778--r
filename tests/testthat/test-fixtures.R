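test_that("infeasible cohort specs fail before anything is generated", {
  expect_error(cohort_spec(freq_range = c(0.5, 0.95), strat_shift = 1.2),
               "infeasible")
  expect_error(cohort_spec(effect_snps = data.frame(index = 1,
                                                    multiplier = 3)),
               "infeasible")
  expect_error(cohort_spec(n_snps = 10,
                           effect_snps = data.frame(index = 11,
                                                    multiplier = 1.5,
                                                    q_ref = 0.01)),
               "out of range")
  expect_error(cohort_spec(n_snps = 10,
                           hwe_snps = data.frame(index = 2,
                                                 het_deficit = -1)),
               "het_deficit")
  expect_error(cohort_spec(freq_range = c(0.4, 0.1)), "increasing")
})

test_that("truth-table frequencies match the realized cohort within MC error", {
  spec <- cohort_spec(n_case = 400, n_control = 400, n_ref = 5000,
                      n_snps = 300, freq_range = c(0.1, 0.4), seed = 10)
  coh <- generate_cohort(spec)
  q_emp_ctrl <- coh$snps$control_alt / coh$snps$control_total
  se <- sqrt(coh$truth$q_control * (1 - coh$truth$q_control) / 800)
  expect_gt(mean(abs(q_emp_ctrl - coh$truth$q_control) <= 4 * se), 0.99)
  q_emp_ref <- coh$reference$ac / coh$reference$an
  se_ref <- sqrt(coh$truth$q_ref * (1 - coh$truth$q_ref) / 10000)
  expect_gt(mean(abs(q_emp_ref - coh$truth$q_ref) <= 4 * se_ref), 0.99)
  # genotype counts are consistent with allele counts
  expect_equal(coh$snps$case_alt,
               2 * coh$snps$case_hom_alt + coh$snps$case_het)
  expect_identical(generate_cohort(spec)$snps, coh$snps)   # reproducible
})

test_that("stratification shift moves study frequencies off the reference", {
  spec <- cohort_spec(n_case = 1000, n_control = 1000, n_ref = 5000,
                      n_snps = 200, freq_range = c(0.2, 0.3),
                      strat_shift = 1.1, seed = 3)
  coh <- generate_cohort(spec)
  expect_equal(coh$truth$q_control, coh$truth$q_ref * 1.1)
  ratio <- mean(coh$snps$control_alt / coh$snps$control_total) /
    mean(coh$reference$ac / coh$reference$an)
  expect_equal(ratio, 1.1, tolerance = 0.02)
})

test_that("planted HWE violations are removed by the filter", {
  spec <- cohort_spec(n_case = 200, n_control = 200, n_ref = 1000,
                      n_snps = 50, freq_range = c(0.2, 0.4),
                      hwe_snps = data.frame(index = 7, het_deficit = 0),
                      seed = 4)
  coh <- generate_cohort(spec)
  expect_equal(coh$snps$control_het[7], 0L)
  f <- hwe_filter(coh$snps)
  expect_true(coh$snps$rsid[7] %in% f$removed$rsid)
})

test_that("a planted effect SNP is detected and reference-powered", {
  spec <- cohort_spec(n_case = 500, n_control = 500, n_ref = 10000,
                      n_snps = 100, freq_range = c(0.05, 0.3),
                      effect_snps = data.frame(index = 1, multiplier = 3,
                                               q_ref = 0.01),
                      seed = 11)
  coh <- generate_cohort(spec)
  joined <- join_reference(coh$snps, coh$reference)
  r <- tidy(run_rrpat(joined, threshold = 1e-3))
  hit <- r[r$rsid == coh$truth$rsid[1], ]
  expect_lt(hit$p_t, 1e-3)
  expect_lt(hit$p_t, hit$p_ca_co)
})

test_that("written cohort files round-trip through the package readers", {
  spec <- cohort_spec(n_case = 40, n_control = 40, n_ref = 500, n_snps = 30,
                      seed = 21)
  coh <- generate_cohort(spec)
  dir <- withr::local_tempdir()
  paths <- write_cohort(coh, dir)
  expect_true(all(file.exists(paths)))
  study <- read_study_vcf(paths["study"], paths["groups"])
  expect_equal(nrow(study), 30L)
  expect_equal(study$case_alt, as.numeric(coh$snps$case_alt))
  expect_equal(study$control_hom_ref, as.numeric(coh$snps$control_hom_ref))
  ref <- read_reference(paths["reference"])
  expect_equal(as.numeric(ref$ac), as.numeric(coh$reference$ac))
  joined <- join_reference(study, ref)
  expect_equal(nrow(joined), 30L)   # generator avoids ambiguous alleles
  truth <- readr::read_tsv(paths["truth"], show_col_types = FALSE)
  expect_equal(nrow(truth), 30L)
})
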