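#' Settings for the maximum-likelihood fit
#'
#' @param n_starts Number of multistart initial points; the likelihood is
#'   multimodal in small samples, so several jittered starts are run and
#'   the best retained (exact ties broken by the lowest start index).
#' @param maxit Iteration cap handed to the optimizer, per start.
#' @param reltol Relative convergence tolerance of the optimizer.
#' @param seed Integer seed driving the start-point jitter; fits are
#'   deterministic given the seed.
#' @param clamp_t0 Apply the two-pass threshold rule: if the unconstrained
#'   optimum has t0 < 0, refit with t0 frozen at 0.
#' @return A list of class \code{"tva_fit_settings"}.
#' @export
fit_settings <- function(n_starts = 20, maxit = 1000, reltol = 1e-10,
                         seed = 1L, clamp_t0 = TRUE) {
  if (n_starts < 1) stop("n_starts must be >= 1")
  if (reltol <= 0) stop("reltol must be positive")
  structure(list(n_starts = as.integer(n_starts), maxit = maxit,
                 reltol = reltol, seed = seed, clamp_t0 = isTRUE(clamp_t0)),
            class = "tva_fit_settings")
}

# theta = (a_1..a_{n-1} capacity log-ratios, log C, t0, log mu);
# when fix_t0, t0 is dropped and frozen at 0.
theta_to_par <- function(theta, n, fix_t0 = FALSE) {
  a <- theta[seq_len(n - 1)]
  C <- exp(theta[n])
  t0 <- if (fix_t0) 0 else theta[n + 1]
  mu <- exp(theta[length(theta)])
  list(k_dist = softmax_simplex(a), C = C, t0 = t0, mu = mu)
}

neg_loglik_factory <- function(counts, conds, n) {
  obs <- counts > 0
  function(theta, fix_t0 = FALSE) {
    p <- theta_to_par(theta, n, fix_t0)
    if (!is.finite(p$C) || p$C <= 0 || p$C > 1e4 || !is.finite(p$mu) ||
        p$mu > 1e4 || !is.finite(p$t0) || abs(p$t0) > 1e4) {
      return(1e10)
    }
    tau <- effective_exposure(conds$exposure_ms, conds$masked, p$t0, p$mu)
    prob <- encoding_probability(p$C, tau, n)
    db <- outer(prob, 0:n, function(pp, m) stats::dbinom(m, n, pp))
    tail_ge <- db[, (n + 1):1, drop = FALSE]
    tail_ge <- t(apply(tail_ge, 1, cumsum))[, (n + 1):1, drop = FALSE]
    surv_gt <- c(rev(cumsum(rev(p$k_dist)))[-1], 0)  # P(K > m), m = 1..n
    pmf <- db
    pmf[, -1] <- db[, -1, drop = FALSE] *
      rep(surv_gt, each = nrow(db)) +
      tail_ge[, -1, drop = FALSE] * rep(p$k_dist, each = nrow(db))
    if (any(obs & pmf <= 0)) return(1e10)
    ll <- sum(counts[obs] * log(pmf[obs]))
    if (!is.finite(ll)) return(1e10)
    -ll
  }
}

# Heuristic central start: t0 at half the shortest exposure, C from the
# initial slope of mean score vs exposure (E[score] ~ C * tau / 1000 for
# small tau), uniform capacity distribution, mu at 60 ms.
start_heuristics <- function(counts, conds, n) {
  mean_score <- as.vector(counts %*% (0:n)) / pmax(rowSums(counts), 1)
  masked <- conds$masked & rowSums(counts) > 0
  C0 <- 20
  if (sum(masked) >= 2) {
    x <- conds$exposure_ms[masked]
    y <- mean_score[masked]
    sl <- stats::cov(x, y) / stats::var(x)
    if (is.finite(sl) && sl > 0) C0 <- min(max(1000 * sl, 2), 200)
  }
  list(a = rep(0, n - 1),
       logC = log(C0),
       t0 = min(conds$exposure_ms) / 2,
       logmu = log(60))
}

run_one_start <- function(theta0, nll, settings, fix_t0) {
  fn <- function(th) nll(th, fix_t0 = fix_t0)
  o1 <- stats::optim(theta0, fn, method = "Nelder-Mead",
                     control = list(maxit = settings$maxit,
                                    reltol = settings$reltol))
  o2 <- tryCatch(
    stats::optim(o1$par, fn, method = "BFGS",
                 control = list(maxit = 200, reltol = settings$reltol)),
    error = function(e) o1)
  if (o2$value <= o1$value) o2 else o1
}

multistart_optim <- function(nll, start, settings, n, fix_t0 = FALSE) {
  base <- c(start$a, start$logC,
            if (!fix_t0) start$t0, start$logmu)
  best <- NULL
  for (s in seq_len(settings$n_starts)) {
    theta0 <- base
    if (s > 1) {  # start 1 is the un-jittered heuristic
      jit_a <- stats::rnorm(n - 1, 0, 0.75)
      theta0 <- base + c(jit_a, stats::rnorm(1, 0, 0.5),
                         if (!fix_t0) stats::rnorm(1, 0, 12),
                         stats::rnorm(1, 0, 0.6))
    }
    o <- run_one_start(theta0, nll, settings, fix_t0)
    if (is.null(best) || o$value < best$value) {
      best <- o
      best$start_index <- s
    }
  }
  if (best$value >= 1e10) {
    stop("optimizer failed to find a finite-likelihood solution in ",
         settings$n_starts, " starts")
  }
  best
}

#' Fit the whole-report race model by maximum likelihood
#'
#' Estimates the 8-df TVA parameter set (capacity distribution over
#' K = 1..display_size, processing speed C, perceptual threshold t0,
#' unmasked-exposure bonus mu) from one session's trials by maximising the
#' multinomial likelihood of the per-condition correct-report score
#' counts. The optimisation runs over transformed parameters (capacity
#' simplex via log-ratios, log C, unconstrained t0, log mu) from several
#' seeded jittered starting points; if the best unconstrained solution has
#' t0 < 0 the data are refitted with t0 frozen at 0 (the reported fit,
#' flagged \code{t0_clamped}).
#'
#' @param x Trials data frame (see \code{\link{read_trials}}) or a
#'   \code{\link{score_table}}.
#' @param design The \code{\link{whole_report_design}} that produced the
#'   trials.
#' @param settings A \code{\link{fit_settings}} object.
#' @return An object of class \code{"tva_fit"} with components
#'   \code{par} (a \code{\link{tva_par}}), \code{logLik},
#'   \code{t0_clamped}, \code{n_trials_fit}, \code{error_rate} (NA when
#'   fitted from a score table), \code{scores}, \code{design},
#'   \code{settings} and \code{start_index}. Supports \code{print},
#'   \code{summary}, \code{coef}, \code{logLik}, \code{predict},
#'   \code{fitted}, \code{residuals}, \code{plot} and \code{simulate}.
#' @examples
#' des <- whole_report_design()
#' truth <- tva_par(c(0, 0, .2, .6, .2, 0), C = 22, t0 = 30, mu = 90)
#' trials <- simulate_session(truth, des, guess_rate = 0, seed = 7)
#' fit <- fit_tva(trials, des, fit_settings(n_starts = 5, seed = 1))
#' coef(fit)
#' @export
fit_tva <- function(x, design, settings = fit_settings()) {
  stopifnot(inherits(design, "wr_design"))
  er <- NA_real_
  if (inherits(x, "score_table")) {
    scores <- x
  } else {
    scores <- score_table(x, design)
    if (!is.null(x$displayed) && !is.null(x$reported)) {
      er <- suppressWarnings(as.numeric(error_rate(x)))
    }
  }
  counts <- unclass(scores)
  conds <- attr(scores, "conditions")
  n <- design$display_size
  if (sum(counts) == 0) stop("score table is empty: nothing to fit")
  used <- rowSums(counts) > 0
  if (length(unique(conds$exposure_ms[used])) < 2) {
    stop("at least two distinct exposure durations are required ",
         "to identify C and t0")
  }
  nll <- neg_loglik_factory(counts, conds, n)
  start <- start_heuristics(counts, conds, n)
  best <- with_seed(settings$seed, {
    b <- multistart_optim(nll, start, settings, n, fix_t0 = FALSE)
    est <- theta_to_par(b$par, n)
    clamped <- FALSE
    if (settings$clamp_t0 && est$t0 < 0) {
      start0 <- list(a = simplex_to_logratio(est$k_dist),
                     logC = log(est$C), t0 = 0, logmu = log(max(est$mu, 1)))
      b <- multistart_optim(nll, start0, settings, n, fix_t0 = TRUE)
      est <- theta_to_par(b$par, n, fix_t0 = TRUE)
      clamped <- TRUE
    }
    list(opt = b, est = est, clamped = clamped)
  })
  par <- tva_par(best$est$k_dist, best$est$C, best$est$t0, best$est$mu)
  structure(
    list(par = par, logLik = -best$opt$value, t0_clamped = best$clamped,
         n_trials_fit = sum(counts), error_rate = er, scores = scores,
         design = design, settings = settings,
         start_index = best$opt$start_index,
         convergence = best$opt$convergence),
    class = "tva_fit")
}

#' @export
print.tva_fit <- function(x, digits = 3, ...) {
  cat("Whole-report TVA fit (", x$n_trials_fit, " trials, logLik ",
      format(x$logLik, digits = 6), ")\n", sep = "")
  cat("  expected K:", format(x$par$expected_K, digits = digits),
      " C:", format(x$par$C, digits = digits), "Hz",
      " t0:", format(x$par$t0, digits = digits), "ms",
      if (x$t0_clamped) "(clamped)",
      " mu:", format(x$par$mu, digits = digits), "ms\n")
  if (!is.na(x$error_rate)) {
    cat("  error rate:", format(x$error_rate, digits = digits), "\n")
  }
  invisible(x)
}

#' @export
coef.tva_fit <- function(object, ...) {
  p <- object$par
  c(K = p$expected_K, C = p$C, t0 = p$t0, mu = p$mu,
    stats::setNames(p$k_dist, paste0("pi", seq_along(p$k_dist))))
}

#' @export
logLik.tva_fit <- function(object, ...) {
  n_df <- length(object$par$k_dist) - 1 + 2 +
    as.integer(!object$t0_clamped)
  structure(object$logLik, df = n_df, nobs = object$n_trials_fit,
            class = "logLik")
}

#' Predicted score distributions of a fit
#'
#' @param object A \code{"tva_fit"}.
#' @param newdata Optional data frame with \code{exposure_ms} and
#'   \code{masked}; defaults to the design's conditions.
#' @param type \code{"pmf"} for the full score distribution per condition,
#'   \code{"mean"} for the expected score.
#' @param ... Unused.
#' @return Matrix of probabilities (conditions x scores) or a numeric
#'   vector of expected scores.
#' @export
predict.tva_fit <- function(object, newdata = NULL,
                            type = c("pmf", "mean"), ...) {
  type <- match.arg(type)
  conds <- if (is.null(newdata)) design_conditions(object$design) else newdata
  n <- object$design$display_size
  pm <- t(vapply(seq_len(nrow(conds)), function(i) {
    score_mixture_pmf(object$par, conds$exposure_ms[i], conds$masked[i],
                      object$design)
  }, numeric(n + 1)))
  colnames(pm) <- paste0("score", 0:n)
  if (type == "pmf") return(pm)
  as.vector(pm %*% (0:n))
}

#' @export
fitted.tva_fit <- function(object, ...) {
  predict(object, type = "mean")
}

#' @export
residuals.tva_fit <- function(object, ...) {
  counts <- unclass(object$scores)
  n <- object$design$display_size
  obs <- as.vector(counts %*% (0:n)) / pmax(rowSums(counts), 1)
  obs - fitted(object)
}

#' @export
summary.tva_fit <- function(object, ...) {
  conds <- attr(object$scores, "conditions")
  counts <- unclass(object$scores)
  n <- object$design$display_size
  tab <- data.frame(
    exposure_ms = conds$exposure_ms, masked = conds$masked,
    n_trials = rowSums(counts),
    observed_mean = as.vector(counts %*% (0:n)) / pmax(rowSums(counts), 1),
    fitted_mean = fitted(object))
  structure(list(fit = object, condition_table = tab),
            class = "summary.tva_fit")
}

#' @export
print.summary.tva_fit <- function(x, digits = 3, ...) {
  print(x$fit, digits = digits)
  cat("\nMean correct report by condition:\n")
  print(x$condition_table, digits = digits, row.names = FALSE)
  invisible(x)
}

#' @export
plot.tva_fit <- function(x, ...) {
  conds <- attr(x$scores, "conditions")
  counts <- unclass(x$scores)
  n <- x$design$display_size
  obs <- as.vector(counts %*% (0:n)) / pmax(rowSums(counts), 1)
  grid <- seq(1, max(conds$exposure_ms) * 1.1, length.out = 80)
  fit_m <- predict(x, data.frame(exposure_ms = grid, masked = TRUE),
                   type = "mean")
  fit_u <- predict(x, data.frame(exposure_ms = grid, masked = FALSE),
                   type = "mean")
  graphics::plot(conds$exposure_ms, obs, ylim = c(0, n),
                 pch = ifelse(conds$masked, 19, 1),
                 xlab = "exposure (ms)", ylab = "mean correct report", ...)
  graphics::lines(grid, fit_m, lty = 1)
  graphics::lines(grid, fit_u, lty = 2)
  graphics::legend("bottomright",
                   c("masked (obs)", "unmasked (obs)", "masked (fit)",
                     "unmasked (fit)"),
                   pch = c(19, 1, NA, NA), lty = c(NA, NA, 1, 2), bty = "n")
  invisible(x)
}

#' Simulate sessions from a fitted model
#'
#' @param object A \code{"tva_fit"}.
#' @param nsim Number of sessions to simulate.
#' @param seed Optional integer seed.
#' @param guess_rate Per-trial intrusion probability handed to
#'   \code{\link{simulate_session}}.
#' @param ... Unused.
#' @return A list of \code{nsim} trial data frames.
#' @export
simulate.tva_fit <- function(object, nsim = 1, seed = NULL,
                             guess_rate = 0, ...) {
  with_seed(seed, lapply(seq_len(nsim), function(i) {
    simulate_session(object$par, object$design, guess_rate = guess_rate)
  }))
}
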