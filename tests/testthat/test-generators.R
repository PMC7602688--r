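test_that("cohort generator honours sizes, seeds and feasibility", {
  cfg <- cohort_config(n_patients = 20, n_controls = 40, seed = 71)
  coh <- generate_cohort(cfg)
  expect_equal(nrow(coh$subjects), 60)
  expect_equal(sum(coh$subjects$group == "control"),
               2 * sum(coh$subjects$group == "patient"))
  expect_true(all(coh$subjects$C > 0))
  expect_true(all(coh$subjects$t0 >= 0))
  expect_true(all(coh$subjects$true_K >= 1 & coh$subjects$true_K <= 6))
  expect_true(all(is.na(coh$subjects$NIHSS[coh$subjects$group == "control"])))
  expect_identical(generate_cohort(cfg)$subjects, coh$subjects)
  expect_false(identical(generate_cohort(cfg, seed = 72)$subjects,
                         coh$subjects))
  expect_error(cohort_config(mean_C = 5, shift_C = -6), "infeasible")
})

test_that("zero shifts and zero noise give identical group expectations", {
  cfg <- cohort_config(n_patients = 15, n_controls = 30,
                       shift_K = 0, shift_C = 0, shift_t0 = 0,
                       shift_error = 0, age_slope_K = 0, age_slope_C = 0,
                       age_slope_t0 = 0, sex_t0 = 0,
                       sd_K = 0, sd_C = 0, sd_t0 = 0, sd_error = 0,
                       noise_K = 0, noise_C = 0, noise_t0 = 0,
                       noise_error = 0, seed = 73)
  coh <- generate_cohort(cfg)
  by_group <- tapply(coh$subjects$true_K, coh$subjects$group, mean)
  expect_equal(unname(diff(by_group)), 0)
  expect_equal(sd(coh$subjects$K), 0)
})

test_that("cohort trials round through the race simulator when asked", {
  cfg <- cohort_config(n_patients = 2, n_controls = 2, seed = 74)
  coh <- generate_cohort(cfg, simulate_trials = TRUE)
  expect_equal(nrow(coh$trials), 4 * 160)
  expect_setequal(unique(coh$trials$subject_id), coh$subjects$subject_id)
})

test_that("longitudinal panel carries trends and targets its ICC", {
  cfg <- longitudinal_config(n_subjects = 150, seed = 75)
  lg <- generate_longitudinal(cfg)
  expect_equal(nrow(lg$sessions), 150 * 6)
  expect_equal(unique(table(lg$sessions$subject_id)), 6L)
  # session means rise by roughly the configured K trend
  mk <- tapply(lg$sessions$K, lg$sessions$session, mean)
  sl <- cov(1:6, mk) / var(1:6)
  expect_lt(abs(sl - 0.090), 0.05)
  # latent ICC without trends or slopes reaches its target
  cfg0 <- longitudinal_config(n_subjects = 400, trend_K = 0,
                              slope_sd_K = 0, icc_K = 0.8, seed = 76)
  lg0 <- generate_longitudinal(cfg0)
  icc <- icc_oneway(lg0$sessions, "K")
  expect_lt(abs(icc$icc - 0.8), 0.05)
})

test_that("noise-free longitudinal values are perfectly reliable", {
  cfg <- longitudinal_config(n_subjects = 30, trend_K = 0, slope_sd_K = 0,
                             icc_K = 1 - 1e-12, seed = 77)
  lg <- generate_longitudinal(cfg)
  icc <- icc_oneway(lg$sessions, "K")
  expect_gt(icc$icc, 0.999)
})

test_that("training curves follow intercept + slope x session exactly when noise-free", {
  cfg <- cogmed_config(n_tasks = 1, residual_sd = 0, intercept_sd = 0,
                       intercept_mean = 10, base_slope = 0.5,
                       loadings = 0.8, seed = 78)
  cg <- generate_cogmed(cfg, n_subjects = 5)
  d <- cg$performance
  for (id in cg$subjects$subject_id) {
    di <- d[d$subject_id == id, ]
    g <- cg$subjects$gain[cg$subjects$subject_id == id]
    expect_equal(di$performance,
                 10 + (0.5 + 0.8 * g) * (di$session - 1),
                 tolerance = 1e-10)
  }
  # default panel dimensions: 10 tasks x 17 sessions per subject
  cg2 <- generate_cogmed(cogmed_config(seed = 79), n_subjects = 3)
  expect_equal(nrow(cg2$performance), 3 * 10 * 17)
  expect_equal(max(cg2$performance$session), 17)
})

test_that("latent gain couples to longitudinal practice slopes", {
  lcfg <- longitudinal_config(n_subjects = 120, slope_sd_K = 0.08,
                              seed = 80)
  lg <- generate_longitudinal(lcfg)
  ccfg <- cogmed_config(coupling = c(K = 1, C = 0, t0 = 0,
                                     error_rate = 0),
                        coupling_noise_sd = 0.2, seed = 81)
  cg <- generate_cogmed(ccfg, longitudinal = lg)
  expect_gt(cor(cg$subjects$gain, lg$subjects$dev_K), 0.7)
})
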