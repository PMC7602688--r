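test_that("fitting recovers generating parameters on pooled sessions", {
  set.seed(51)
  trials <- do.call(rbind, lapply(1:5, function(i) {
    simulate_session(ref_par, std_design, guess_rate = 0,
                     subject_id = sprintf("s%d", i))
  }))
  fit <- fit_tva(trials, std_design, quick_settings)
  expect_s3_class(fit, "tva_fit")
  expect_lt(abs(fit$par$expected_K - 4), 0.3)
  expect_lt(abs(fit$par$C - 22) / 22, 0.2)
  expect_lt(abs(fit$par$t0 - 30), 12)
  expect_equal(fit$n_trials_fit, 700)
  # the MLE cannot fall below the likelihood at the generating truth
  st <- score_table(trials, std_design)
  expect_gte(fit$logLik, session_loglik(ref_par, st, std_design))
})

test_that("fits are deterministic given the settings seed", {
  trials <- simulate_session(ref_par, std_design, guess_rate = 0, seed = 52)
  f1 <- fit_tva(trials, std_design, fit_settings(n_starts = 3, seed = 9))
  f2 <- fit_tva(trials, std_design, fit_settings(n_starts = 3, seed = 9))
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$logLik, f2$logLik)
})

test_that("degenerate inputs are rejected with informative errors", {
  trials <- simulate_session(ref_par, std_design, guess_rate = 0, seed = 53)
  one_cond <- trials[trials$exposure_ms == 200 & trials$masked &
                       !trials$is_practice, ]
  expect_error(fit_tva(one_cond, std_design, quick_settings),
               "two distinct exposure durations")
  conds <- design_conditions(std_design)
  empty <- score_table_from_counts(matrix(0, 7, 7), conds)
  expect_error(fit_tva(empty, std_design, quick_settings), "empty")
})

test_that("the threshold clamp refits at zero and never goes negative", {
  zero_t0 <- tva_par(c(0, 0, .2, .6, .2, 0), C = 22, t0 = 0, mu = 90)
  fits <- lapply(1:4, function(r) {
    trials <- simulate_session(zero_t0, std_design, guess_rate = 0,
                               seed = 600 + r)
    fit_tva(trials, std_design, fit_settings(n_starts = 5, seed = r))
  })
  t0s <- vapply(fits, function(f) f$par$t0, numeric(1))
  clamped <- vapply(fits, function(f) f$t0_clamped, logical(1))
  expect_true(all(t0s >= 0))
  expect_true(all(t0s[clamped] == 0))
})

test_that("fit methods expose coefficients, predictions and residuals", {
  trials <- simulate_session(ref_par, std_design, guess_rate = 0.05,
                             seed = 54)
  fit <- fit_tva(trials, std_design, quick_settings)
  cf <- coef(fit)
  expect_named(cf, c("K", "C", "t0", "mu", paste0("pi", 1:6)))
  expect_equal(sum(cf[paste0("pi", 1:6)]), 1, tolerance = 1e-9)
  pm <- predict(fit)
  expect_equal(dim(pm), c(7, 7))
  expect_equal(unname(rowSums(pm)), rep(1, 7), tolerance = 1e-9)
  expect_length(residuals(fit), 7)
  expect_equal(fitted(fit) + residuals(fit),
               as.vector(unclass(fit$scores) %*% (0:6)) / 20,
               tolerance = 1e-9)
  ll <- logLik(fit)
  expect_equal(attr(ll, "df"), if (fit$t0_clamped) 7 else 8)
  sims <- simulate(fit, nsim = 2, seed = 3)
  expect_length(sims, 2)
  expect_equal(nrow(sims[[1]]), 160)
  expect_output(print(summary(fit)), "Mean correct report")
})
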