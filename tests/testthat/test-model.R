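test_that("effective exposure truncates at zero and credits mu when unmasked", {
  expect_equal(effective_exposure(200, TRUE, t0 = 200, mu = 0), 0)
  expect_equal(effective_exposure(40, FALSE, t0 = 20, mu = 100), 120)
  expect_equal(effective_exposure(20, TRUE, t0 = 32.41, mu = 50), 0)
  # vectorised over conditions
  expect_equal(effective_exposure(c(20, 40), c(TRUE, FALSE), 10, 5),
               c(10, 35))
})

test_that("encoding probability follows the exponential race rate", {
  expect_equal(encoding_probability(30, 0, 6), 0)
  expect_equal(encoding_probability(30, 200, 6), 1 - exp(-1))
  expect_lt(abs(encoding_probability(1e6, 200, 6) - 1), 1e-12)
  expect_error(encoding_probability(0, 100, 6), "positive")
  expect_error(encoding_probability(-5, 100, 6), "positive")
  # strictly increasing in C and in tau
  set.seed(41)
  for (i in 1:20) {
    C <- runif(1, 5, 60); tau <- runif(1, 10, 300)
    expect_gt(encoding_probability(C + 1, tau, 6),
              encoding_probability(C, tau, 6))
    expect_gt(encoding_probability(C, tau + 1, 6),
              encoding_probability(C, tau, 6))
  }
})

test_that("capacity-truncated score pmf matches binomial-tail enumeration", {
  expect_equal(score_pmf(0.5, 2, 6), c(1, 6, 57, 0, 0, 0, 0) / 64)
  expect_equal(score_pmf(0, 3, 6), c(1, rep(0, 6)))
  # capacity never binds at k = n: plain binomial
  expect_equal(score_pmf(0.3, 6, 6), dbinom(0:6, 6, 0.3))
  expect_error(score_pmf(0.5, 0, 6), "k must lie")
  expect_error(score_pmf(0.5, 7, 6), "k must lie")
  set.seed(42)
  for (i in 1:50) {
    p <- runif(1); k <- sample(6, 1)
    v <- score_pmf(p, k, 6)
    expect_equal(sum(v), 1, tolerance = 1e-12)
    expect_true(all(v[(k + 2):7] == 0) || k == 6)
    expect_true(all(v >= 0))
  }
})

test_that("mixture pmf equals the capacity-weighted sum of score pmfs", {
  # degenerate mixture reduces to a single capacity
  pm <- tva_par(c(0, 0, 0, 0, 0, 1), C = 30, t0 = 0, mu = 0)
  expect_equal(score_mixture_pmf(pm, 200, TRUE, std_design),
               score_pmf(1 - exp(-1), 6, 6))
  set.seed(43)
  for (i in 1:25) {
    par <- random_par()
    cond <- design_conditions(std_design)[sample(7, 1), ]
    v <- score_mixture_pmf(par, cond$exposure_ms, cond$masked, std_design)
    p <- encoding_probability(
      par$C, effective_exposure(cond$exposure_ms, cond$masked,
                                par$t0, par$mu), 6)
    brute <- Reduce(`+`, lapply(1:6, function(k) {
      par$k_dist[k] * score_pmf(p, k, 6)
    }))
    expect_equal(v, brute, tolerance = 1e-12)
    expect_equal(sum(v), 1, tolerance = 1e-12)
  }
  # threshold above every masked exposure: nothing encoded
  blind <- tva_par(rep(1 / 6, 6), C = 30, t0 = 250, mu = 0)
  for (e in std_design$masked_exposures) {
    expect_equal(score_mixture_pmf(blind, e, TRUE, std_design),
                 c(1, rep(0, 6)))
  }
})

test_that("expected score is monotone in exposure, speed and capacity order", {
  mean_score <- function(par, e) {
    sum(0:6 * score_mixture_pmf(par, e, TRUE, std_design))
  }
  set.seed(44)
  for (i in 1:15) {
    par <- random_par()
    es <- sapply(c(20, 40, 60, 110, 200), mean_score, par = par)
    expect_true(all(diff(es) >= -1e-12))
    faster <- tva_par(par$k_dist, par$C * 1.5, par$t0, par$mu)
    expect_gte(mean_score(faster, 110), mean_score(par, 110) - 1e-12)
    # shifting capacity mass upward (stochastic dominance) cannot hurt
    kd <- par$k_dist
    j <- which(kd[-6] > 0)[1]
    if (!is.na(j)) {
      kd2 <- kd
      kd2[j] <- 0
      kd2[j + 1] <- kd[j + 1] + kd[j]
      dom <- tva_par(kd2, par$C, par$t0, par$mu)
      expect_gte(mean_score(dom, 110), mean_score(par, 110) - 1e-12)
    }
  }
})

test_that("expected capacity is the dot product over the support", {
  expect_equal(expected_K(c(0, 0, 0, 0, 0, 1)), 6)
  expect_equal(expected_K(rep(1 / 6, 6)), 3.5)
  expect_equal(expected_K(c(0, 0, .2, .6, .2, 0)), 4)
  expect_error(expected_K(c(0.5, 0.2)), "summing to 1")
  expect_error(expected_K(c(-0.1, 1.1)), "probability")
})

test_that("session log-likelihood counts log model probabilities", {
  conds <- design_conditions(std_design)
  # params that encode nothing, data all zero: every trial has probability 1
  blind <- tva_par(rep(1 / 6, 6), C = 30, t0 = 500, mu = 0)
  zero_tab <- score_table_from_counts(
    cbind(rep(20, 5), matrix(0, 5, 6)), conds[conds$masked, ])
  expect_equal(session_loglik(blind, zero_tab, std_design), 0)
  # observed score above supported capacity: impossible
  low <- tva_par(c(1, 0, 0, 0, 0, 0), C = 30, t0 = 0, mu = 0)
  two_tab <- score_table_from_counts(
    cbind(0, 0, rep(20, 5), matrix(0, 5, 4)), conds[conds$masked, ])
  expect_equal(session_loglik(low, two_tab, std_design), -Inf)
  # 20 trials all scoring 2 with P(2) = 57/64
  p_half <- 6 * log(2) / 0.2   # C making p = 0.5 at 200 ms, t0 = 0
  par2 <- tva_par(c(0, 1, 0, 0, 0, 0), C = p_half, t0 = 0, mu = 0)
  one_cond <- score_table_from_counts(
    matrix(c(0, 0, 20, 0, 0, 0, 0), 1),
    data.frame(exposure_ms = 200, masked = TRUE))
  expect_equal(session_loglik(par2, one_cond, std_design),
               20 * log(57 / 64), tolerance = 1e-9)
  # condition mismatch is rejected
  bad <- score_table_from_counts(matrix(c(0, 0, 20, 0, 0, 0, 0), 1),
                                 data.frame(exposure_ms = 999,
                                            masked = TRUE))
  expect_error(session_loglik(par2, bad, std_design), "do not match")
})

test_that("score table accumulates per-condition counts and drops practice", {
  trials <- simulate_session(ref_par, std_design, guess_rate = 0, seed = 5)
  st <- score_table(trials, std_design)
  expect_equal(unname(rowSums(st)), rep(20, 7))
  expect_equal(sum(st), 140)
  conds <- attr(st, "conditions")
  expect_equal(nrow(conds), 7)
  expect_error(score_table(trials[trials$is_practice, ], std_design),
               "no non-practice")
})

test_that("error rate is intrusions over reported letters", {
  # 10 trials, each 3 correct + 1 intrusion: 10/40
  tr <- make_trials(rep("ABDEFG", 10),
                    rep("ABDZ", 10))
  expect_equal(error_rate(tr), 0.25)
  all_ok <- make_trials(rep("ABDEFG", 5), rep("ABD", 5))
  expect_equal(error_rate(all_ok), 0)
  expect_error(error_rate(make_trials(character(0), character(0))),
               "empty")
  silent <- make_trials(rep("ABDEFG", 3), rep("", 3))
  expect_warning(er <- error_rate(silent), "no letters reported")
  expect_equal(as.numeric(er), 0)
  # practice trials never count
  mixed <- rbind(make_trials("ABDEFG", "AZ", is_practice = TRUE),
                 make_trials("ABDEFG", "AB"))
  expect_equal(error_rate(mixed), 0)
})
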