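test_that("Cohen's d reproduces 2t/sqrt(df) with sign", {
  expect_equal(round(cohens_d_from_t(-3.207, 206), 3), -0.447)
  expect_equal(round(cohens_d_from_t(-3.321, 206), 3), -0.463)
  expect_equal(cohens_d_from_t(0, 100), 0)
  expect_error(cohens_d_from_t(2, 0), "positive")
  expect_error(cohens_d_from_t(2, -5), "positive")
})

test_that("linear models return classical inference and effect sizes", {
  d <- data.frame(x = 1:10)
  d$y <- 2 * d$x + 1
  fit <- suppressWarnings(tva_lm(y ~ x, d))
  expect_equal(fit$coefficients$estimate, c(1, 2), tolerance = 1e-10)
  expect_equal(fit$sigma, 0, tolerance = 1e-10)
  # residual df bookkeeping: n = 210, intercept + group + age + sex
  set.seed(61)
  d2 <- data.frame(group = gl(2, 105), age = rnorm(210, 60, 8),
                   sex = gl(2, 1, 210), y = rnorm(210))
  fit2 <- tva_lm(y ~ group + age + sex, d2)
  expect_equal(fit2$df_residual, 206)
  expect_equal(fit2$coefficients$cohens_d,
               cohens_d_from_t(fit2$coefficients$t, 206))
  # collinear columns are named
  d2$age2 <- d2$age
  expect_error(tva_lm(y ~ age + age2, d2), "age2")
})

test_that("permuted outcomes give uniform group p-values", {
  set.seed(62)
  n <- 40
  d <- data.frame(group = gl(2, n / 2), age = rnorm(n, 60, 8),
                  sex = gl(2, 1, n))
  ps <- replicate(200, {
    d$y <- rnorm(n)
    fit <- tva_lm(y ~ group + age + sex, d)
    fit$coefficients$p[fit$coefficients$term == "group2"]
  })
  # rejection rate at 0.05 within its binomial 99% band for 200 draws
  expect_gte(sum(ps < 0.05), qbinom(0.005, 200, 0.05))
  expect_lte(sum(ps < 0.05), qbinom(0.995, 200, 0.05))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("2x2 chi-square matches the closed form without correction", {
  res <- chi_square_2x2(rbind(c(55, 85), c(20, 50)))
  expect_equal(res$statistic, 210 * (55 * 50 - 85 * 20)^2 /
                 (140 * 70 * 75 * 135), tolerance = 1e-12)
  expect_equal(round(res$statistic, 2), 2.33)
  expect_equal(round(res$p, 3), 0.127)
  expect_equal(chi_square_2x2(rbind(c(10, 20), c(30, 60)))$statistic, 0)
  expect_equal(chi_square_2x2(rbind(c(10, 0), c(0, 10)))$statistic, 20)
  expect_error(chi_square_2x2(rbind(c(0, 0), c(1, 2))), "margins")
})

test_that("Welch t agrees between summary and raw-vector routes", {
  res <- welch_t(list(mean = 15.92, sd = 3.22, n = 140),
                 list(mean = 14.27, sd = 3.78, n = 70))
  expect_equal(res$t, 3.128, tolerance = 5e-4)
  set.seed(63)
  x <- rnorm(30, 1, 2); y <- rnorm(50, 0, 3)
  mine <- welch_t(x, y)
  ref <- t.test(x, y)
  expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-10)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  # equal summaries: t = 0; doubling both n scales |t| by sqrt(2)
  expect_equal(welch_t(list(mean = 1, sd = 1, n = 10),
                       list(mean = 1, sd = 1, n = 10))$t, 0)
  t1 <- welch_t(list(mean = 2, sd = 1, n = 10),
                list(mean = 1, sd = 2, n = 20))$t
  t2 <- welch_t(list(mean = 2, sd = 1, n = 20),
                list(mean = 1, sd = 2, n = 40))$t
  expect_equal(t2 / t1, sqrt(2), tolerance = 1e-10)
})

test_that("one-way ICC equals the ANOVA estimator on a hand example", {
  m <- rbind(c(1, 2), c(4, 6), c(7, 9))
  res <- icc_oneway(m)
  # MSB = 21.1667, MSW = 1.5, k0 = 2 (hand ANOVA arithmetic)
  msb <- 2 * sum((rowMeans(m) - mean(m))^2) / 2
  msw <- sum((m - rowMeans(m))^2) / 3
  expect_equal(res$icc, (msb - msw) / (msb + msw), tolerance = 1e-12)
  expect_equal(res$icc, 0.8676471, tolerance = 1e-6)
  # cross-check mean squares against aov
  long <- data.frame(y = as.vector(m), s = factor(rep(1:3, 2)))
  ms <- summary(stats::aov(y ~ s, long))[[1]]$`Mean Sq`
  expect_equal((ms[1] - ms[2]) / (ms[1] + ms[2]), res$icc,
               tolerance = 1e-12)
})

test_that("ICC degenerate and error cases behave", {
  perfect <- rbind(c(1, 1), c(5, 5), c(9, 9))
  res <- icc_oneway(perfect)
  expect_equal(res$icc, 1)
  expect_equal(res$upper, 1)
  expect_error(icc_oneway(matrix(3, 4, 2)), "identical")
  expect_error(icc_oneway(matrix(1:2, 1, 2)), "two subjects")
})

test_that("ICC recovers a known variance ratio and its CI covers it", {
  set.seed(64)
  n <- 200; k <- 6
  b <- rnorm(n, 0, sqrt(3))
  m <- matrix(b, n, k) + matrix(rnorm(n * k), n, k)
  res <- icc_oneway(m)
  expect_lt(abs(res$icc - 0.75), 0.07)
  expect_lt(res$lower, 0.75)
  expect_gt(res$upper, 0.75)
  # long-format route agrees with the matrix route
  long <- data.frame(subject_id = rep(seq_len(n), k),
                     session = rep(seq_len(k), each = n),
                     K = as.vector(m))
  expect_equal(icc_oneway(long, "K")$icc, res$icc, tolerance = 1e-12)
})

test_that("per-subject slopes are OLS on the session index", {
  d <- data.frame(subject_id = rep(c("a", "b"), each = 6),
                  session = rep(1:6, 2))
  d$y <- ifelse(d$subject_id == "a", d$session, 5)
  s <- subject_slopes(d, "y")
  expect_equal(s$slope_y, c(1, 0))
  set.seed(65)
  d$z <- 2 * d$session + rnorm(12, 0, 0.01)
  s2 <- subject_slopes(d, c("y", "z"))
  expect_true(all(abs(s2$slope_z - 2) < 0.02))
})
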