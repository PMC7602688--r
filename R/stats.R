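#' Cohen's d from a linear-model t statistic
#'
#' Effect size computed as two times the t value divided by the square
#' root of the residual degrees of freedom; the sign of t is preserved.
#'
#' @param t t statistic.
#' @param df Residual degrees of freedom (> 0).
#' @return Cohen's d. Vectorised over \code{t}.
#' @examples
#' cohens_d_from_t(-3.207, 206)   # -0.447
#' @export
cohens_d_from_t <- function(t, df) {
  if (any(df <= 0)) stop("df must be positive")
  2 * t / sqrt(df)
}

#' Linear model with effect sizes
#'
#' Ordinary least squares via \code{\link[stats]{lm}}, returning a tidy
#' coefficient table with classical standard errors, t statistics,
#' two-sided p values from the t distribution on the residual df, and
#' Cohen's d per coefficient (2t / sqrt(df)). A rank-deficient design is
#' an error naming the collinear columns.
#'
#' @param formula Model formula.
#' @param data Data frame.
#' @return An object of class \code{"tva_lm"}: list with
#'   \code{coefficients} (term, estimate, std_error, t, p, cohens_d),
#'   \code{df_residual}, \code{sigma}, \code{f_statistic}
#'   (value, df1, df2, p) and the underlying \code{lm} object.
#' @export
tva_lm <- function(formula, data) {
  fit <- stats::lm(formula, data = data)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  sm <- summary(fit)
  ct <- sm$coefficients
  dfres <- fit$df.residual
  coefs <- data.frame(
    term = rownames(ct), estimate = ct[, 1], std_error = ct[, 2],
    t = ct[, 3], p = ct[, 4],
    cohens_d = cohens_d_from_t(ct[, 3], dfres),
    row.names = NULL, stringsAsFactors = FALSE)
  fstat <- if (is.null(sm$fstatistic)) NULL else {
    fs <- sm$fstatistic
    list(value = unname(fs[1]), df1 = unname(fs[2]), df2 = unname(fs[3]),
         p = stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE))
  }
  structure(list(coefficients = coefs, df_residual = dfres,
                 sigma = sm$sigma, f_statistic = fstat, lm = fit),
            class = "tva_lm")
}

#' @export
print.tva_lm <- function(x, digits = 3, ...) {
  cat("Linear model (residual df ", x$df_residual, ")\n", sep = "")
  print(x$coefficients, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Pearson chi-square test for a 2x2 table
#'
#' Without continuity correction; p value from the chi-square distribution
#' with one degree of freedom.
#'
#' @param counts 2x2 matrix (or something coercible) of counts; all row
#'   and column margins must be positive.
#' @return List with \code{statistic}, \code{p} and \code{df = 1}.
#' @examples
#' chi_square_2x2(rbind(c(55, 85), c(20, 50)))
#' @export
chi_square_2x2 <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == 2)) stop("counts must be a 2x2 table")
  if (any(rowSums(counts) <= 0) || any(colSums(counts) <= 0)) {
    stop("all margins must be positive")
  }
  ht <- stats::chisq.test(counts, correct = FALSE)
  list(statistic = unname(ht$statistic), p = unname(ht$p.value), df = 1)
}

#' Welch two-sample t test
#'
#' Unequal-variance t with Welch-Satterthwaite degrees of freedom, from
#' raw vectors or from (mean, sd, n) summaries.
#'
#' @param x,y Numeric vectors, or lists/named vectors with elements
#'   \code{mean}, \code{sd}, \code{n}.
#' @return List with \code{t}, \code{df} and \code{p} (two-sided).
#' @examples
#' welch_t(list(mean = 15.92, sd = 3.22, n = 140),
#'         list(mean = 14.27, sd = 3.78, n = 70))
#' @export
welch_t <- function(x, y) {
  summarize <- function(v) {
    if (is.list(v) || !is.null(names(v))) {
      list(mean = v[["mean"]], sd = v[["sd"]], n = v[["n"]])
    } else {
      list(mean = mean(v), sd = stats::sd(v), n = length(v))
    }
  }
  a <- summarize(x)
  b <- summarize(y)
  se2a <- a$sd^2 / a$n
  se2b <- b$sd^2 / b$n
  t <- (a$mean - b$mean) / sqrt(se2a + se2b)
  df <- (se2a + se2b)^2 /
    (se2a^2 / (a$n - 1) + se2b^2 / (b$n - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' One-way random-effects intraclass correlation
#'
#' Test-retest reliability across repeated sessions: the between-subject
#' share of variance from a one-way random-effects ANOVA,
#' ICC = (MSB - MSW) / (MSB + (k0 - 1) MSW), where k0 is the (average)
#' number of sessions per subject adjusted for imbalance. The 95%
#' confidence interval is Searle's F interval. Missing cells are allowed;
#' sessions are treated as exchangeable replicates, not fixed raters.
#'
#' @param values Numeric matrix, subjects in rows, sessions in columns
#'   (NAs allowed), or a long data frame with columns \code{subject_id},
#'   \code{session} and the outcome named by \code{outcome}.
#' @param outcome Outcome column name when \code{values} is a data frame.
#' @param conf_level Confidence level for the interval.
#' @return List of class \code{"tva_icc"}: \code{icc}, \code{lower},
#'   \code{upper}, \code{var_between}, \code{var_within}, \code{n_subjects},
#'   \code{k0}. The point estimate is not truncated; negative values are a
#'   reporting-layer choice.
#' @export
icc_oneway <- function(values, outcome = NULL, conf_level = 0.95) {
  if (is.data.frame(values)) {
    if (is.null(outcome)) stop("outcome column must be named for data frames")
    g <- factor(values$subject_id)
    y <- values[[outcome]]
  } else {
    m <- as.matrix(values)
    g <- factor(rep(seq_len(nrow(m)), ncol(m)))
    y <- as.vector(m)
  }
  keep <- !is.na(y)
  y <- y[keep]
  g <- droplevels(g[keep])
  a <- nlevels(g)
  if (a < 2) stop("at least two subjects are required")
  ni <- as.vector(table(g))
  if (all(ni < 2)) stop("at least one subject needs two or more sessions")
  N <- length(y)
  gm <- mean(y)
  mi <- tapply(y, g, mean)
  ssb <- sum(ni * (mi - gm)^2)
  ssw <- sum((y - mi[g])^2)
  msb <- ssb / (a - 1)
  msw <- ssw / (N - a)
  k0 <- (N - sum(ni^2) / N) / (a - 1)
  if (msw == 0 && msb == 0) {
    stop("all values identical: ICC is undefined (0/0)")
  }
  icc <- (msb - msw) / (msb + (k0 - 1) * msw)
  alpha <- 1 - conf_level
  if (msw > 0) {
    Fobs <- msb / msw
    Fu <- stats::qf(1 - alpha / 2, a - 1, N - a)
    Fl <- stats::qf(1 - alpha / 2, N - a, a - 1)
    lower <- (Fobs / Fu - 1) / (Fobs / Fu + k0 - 1)
    upper <- (Fobs * Fl - 1) / (Fobs * Fl + k0 - 1)
  } else {
    lower <- upper <- 1
  }
  structure(list(icc = icc, lower = lower, upper = upper,
                 var_between = (msb - msw) / k0, var_within = msw,
                 n_subjects = a, k0 = k0, conf_level = conf_level),
            class = "tva_icc")
}

#' @export
print.tva_icc <- function(x, digits = 3, ...) {
  cat("One-way intraclass correlation: ",
      format(x$icc, digits = digits), " (",
      round(100 * x$conf_level), "% CI ",
      format(x$lower, digits = digits), " to ",
      format(x$upper, digits = digits), "), ",
      x$n_subjects, " subjects\n", sep = "")
  invisible(x)
}

#' Per-subject session slopes
#'
#' Ordinary least-squares slope of each outcome on the session index
#' (coded as given, by convention 1..S), one regression per subject.
#'
#' @param data Long data frame with \code{subject_id}, \code{session} and
#'   the outcome columns.
#' @param outcomes Character vector of outcome column names.
#' @return Data frame with \code{subject_id} and one slope column per
#'   outcome, named \code{slope_<outcome>}.
#' @export
subject_slopes <- function(data, outcomes) {
  ids <- unique(data$subject_id)
  out <- data.frame(subject_id = ids, stringsAsFactors = FALSE)
  for (oc in outcomes) {
    out[[paste0("slope_", oc)]] <- vapply(ids, function(id) {
      d <- data[data$subject_id == id, ]
      if (nrow(d) < 2 || stats::var(d$session) == 0) return(NA_real_)
      stats::cov(d$session, d[[oc]]) / stats::var(d$session)
    }, numeric(1))
  }
  out
}
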