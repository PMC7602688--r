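#' Bonferroni significance flag
#'
#' @param p Vector of p values.
#' @param m Number of tests in the family.
#' @param alpha Family-wise error rate.
#' @return Logical vector: \code{p < alpha / m}.
#' @export
bonferroni_flag <- function(p, m, alpha = 0.05) {
  if (m < 1) stop("m must be >= 1")
  p < alpha / m
}

#' Case-control comparison of attention parameters
#'
#' One linear model per outcome with group (patient vs control) as the
#' predictor of interest and age and sex as covariates (optionally also
#' education). Significance is flagged at the Bonferroni-corrected level
#' alpha / m where m is the number of outcomes (0.05 / 4 by default).
#'
#' @param subjects Cohort data frame with \code{group}, \code{age},
#'   \code{sex} (and \code{education} if requested) plus the outcome
#'   columns.
#' @param outcomes Outcome column names (default the four whole-report
#'   outcomes).
#' @param include_education Add education as an extra covariate.
#' @param alpha Family-wise error rate.
#' @return Object of class \code{"tva_stage"}: data frame of per-outcome
#'   coefficient rows (outcome, term, estimate, std_error, t, p,
#'   cohens_d, significant) with attributes \code{alpha} and \code{m}.
#' @export
case_control_stage <- function(subjects,
                               outcomes = c("K", "C", "t0", "error_rate"),
                               include_education = FALSE, alpha = 0.05) {
  m <- length(outcomes)
  rhs <- "group + age + sex"
  if (include_education) rhs <- paste(rhs, "+ education")
  res <- do.call(rbind, lapply(outcomes, function(oc) {
    fit <- tva_lm(stats::as.formula(paste(oc, "~", rhs)), subjects)
    cbind(outcome = oc, fit$coefficients,
          df_residual = fit$df_residual)
  }))
  res$significant <- bonferroni_flag(res$p, m, alpha)
  structure(res, alpha = alpha, m = m, class = c("tva_stage", "data.frame"))
}

#' Clinical associations within the patient group
#'
#' For each outcome: the continuous stroke-severity score (NIHSS) is
#' tested by its linear-model t statistic with age and sex as covariates;
#' the categorical predictors (stroke-subtype class, lesion location) are
#' tested by the nested-model F statistic comparing the model with the
#' predictor against the covariate-only model. Categorical levels with
#' fewer than two subjects are dropped with a warning; a predictor left
#' with a single level is an error.
#'
#' @param patients Patient-only data frame with \code{NIHSS},
#'   \code{TOAST}, \code{lesion_location}, \code{age}, \code{sex} and the
#'   outcomes.
#' @param outcomes Outcome column names.
#' @return Data frame with one row per outcome x predictor: for NIHSS the
#'   estimate, std_error, t, p and Cohen's d; for categorical predictors
#'   the F statistic with its df and p.
#' @export
clinical_association_stage <- function(patients,
                                       outcomes = c("K", "C", "t0",
                                                    "error_rate")) {
  prep_cat <- function(x, name) {
    x <- factor(x)
    small <- names(which(table(x) < 2))
    if (length(small)) {
      warning("dropping ", name, " level(s) with < 2 subjects: ",
              paste(small, collapse = ", "))
      x[x %in% small] <- NA
      x <- droplevels(x)
    }
    if (nlevels(x) < 2) {
      stop(name, " has a single level after dropping: no contrast to test")
    }
    x
  }
  rows <- list()
  for (oc in outcomes) {
    d <- patients[!is.na(patients$NIHSS), ]
    fit <- tva_lm(stats::as.formula(paste(oc, "~ NIHSS + age + sex")), d)
    cr <- fit$coefficients[fit$coefficients$term == "NIHSS", ]
    rows[[length(rows) + 1]] <- data.frame(
      outcome = oc, predictor = "NIHSS", estimate = cr$estimate,
      std_error = cr$std_error, t = cr$t, p = cr$p,
      cohens_d = cr$cohens_d, F = NA, df1 = NA, df2 = NA,
      stringsAsFactors = FALSE)
    for (pred in c("TOAST", "lesion_location")) {
      d <- patients[!is.na(patients[[pred]]), ]
      d[[pred]] <- prep_cat(d[[pred]], pred)
      d <- d[!is.na(d[[pred]]), ]
      full <- stats::lm(stats::as.formula(paste(oc, "~", pred,
                                                "+ age + sex")), d)
      red <- stats::lm(stats::as.formula(paste(oc, "~ age + sex")), d)
      an <- stats::anova(red, full)
      rows[[length(rows) + 1]] <- data.frame(
        outcome = oc, predictor = pred, estimate = NA, std_error = NA,
        t = NA, p = an$`Pr(>F)`[2], cohens_d = NA, F = an$F[2],
        df1 = an$Df[2], df2 = full$df.residual, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Training-gain composite from task trajectories
#'
#' Quantifies each subject's improvement over the training programme:
#' per-task per-subject linear slopes of performance on session, slopes
#' z-scored within task, and the first principal component of the
#' resulting subject x task slope matrix taken as the individual gain
#' score. The component sign is fixed so that the mean loading is
#' positive (a higher score means more improvement). Tasks with zero
#' slope variance are dropped with a warning.
#'
#' @param performance Long data frame with \code{subject_id}, \code{task},
#'   \code{session}, \code{performance}.
#' @return Object of class \code{"cogmed_gain"}: list with \code{scores}
#'   (subject_id, gain), \code{loadings}, \code{var_explained},
#'   \code{slopes} (subject x task matrix of raw slopes).
#' @export
cogmed_gain <- function(performance) {
  tasks <- unique(performance$task)
  if (length(tasks) < 1) stop("no tasks in performance table")
  ids <- unique(performance$subject_id)
  slopes <- sapply(tasks, function(tk) {
    d <- performance[performance$task == tk,
                     c("subject_id", "session", "performance")]
    s <- subject_slopes(d, "performance")
    s$slope_performance[match(ids, s$subject_id)]
  })
  slopes <- matrix(slopes, nrow = length(ids),
                   dimnames = list(ids, tasks))
  v <- apply(slopes, 2, stats::var, na.rm = TRUE)
  drop <- v == 0 | is.na(v)
  if (any(drop)) {
    warning("dropping zero-variance task(s): ",
            paste(tasks[drop], collapse = ", "))
  }
  z <- scale(slopes[, !drop, drop = FALSE])
  if (ncol(z) < 1) stop("no tasks with slope variance remain")
  if (ncol(z) == 1) {
    scores <- as.vector(z)
    loadings <- stats::setNames(1, colnames(z))
    ve <- 1
  } else {
    pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
    sgn <- if (mean(pc$rotation[, 1]) < 0) -1 else 1
    scores <- sgn * pc$x[, 1]
    loadings <- sgn * pc$rotation[, 1]
    ve <- pc$sdev[1]^2 / sum(pc$sdev^2)
  }
  structure(list(
    scores = data.frame(subject_id = ids, gain = unname(scores),
                        stringsAsFactors = FALSE),
    loadings = loadings, var_explained = ve, slopes = slopes),
    class = "cogmed_gain")
}

#' @export
print.cogmed_gain <- function(x, digits = 3, ...) {
  cat("Training-gain composite over", length(x$loadings), "tasks;",
      "PC1 explains", format(100 * x$var_explained, digits = digits),
      "% of slope variance\n")
  invisible(x)
}

#' Training gain versus baseline attention performance
#'
#' One linear model per baseline outcome with the training-gain score as
#' dependent variable and age and sex as covariates; optionally with the
#' stimulation arm and its interaction with the baseline outcome.
#'
#' @param gain A \code{\link{cogmed_gain}} object or a data frame with
#'   \code{subject_id} and \code{gain}.
#' @param baseline Data frame with \code{subject_id}, \code{age},
#'   \code{sex} (and \code{arm} when requested) plus the outcome columns
#'   at the first session.
#' @param outcomes Baseline outcome column names.
#' @param include_arm Add arm and arm x outcome interaction terms.
#' @param alpha Family-wise error rate (Bonferroni over the outcomes).
#' @return Object of class \code{"tva_stage"} as in
#'   \code{\link{case_control_stage}}.
#' @export
gain_vs_baseline <- function(gain, baseline,
                             outcomes = c("K", "C", "t0", "error_rate"),
                             include_arm = FALSE, alpha = 0.05) {
  if (inherits(gain, "cogmed_gain")) gain <- gain$scores
  d <- merge(gain, baseline, by = "subject_id")
  m <- length(outcomes)
  res <- do.call(rbind, lapply(outcomes, function(oc) {
    rhs <- paste(oc, "+ age + sex")
    if (include_arm) rhs <- paste(rhs, "+ arm +", oc, ":arm")
    fit <- tva_lm(stats::as.formula(paste("gain ~", rhs)), d)
    cbind(outcome = oc, fit$coefficients, df_residual = fit$df_residual)
  }))
  res$significant <- bonferroni_flag(res$p, m, alpha)
  structure(res, alpha = alpha, m = m, class = c("tva_stage", "data.frame"))
}

#' Correlations between parameter change and training gain
#'
#' Product-moment correlations between per-subject attention-parameter
#' session slopes and the training-gain score, with two-sided p values
#' and their -log10 transform.
#'
#' @param slopes Data frame from \code{\link{subject_slopes}} (columns
#'   \code{subject_id} and \code{slope_*}).
#' @param gain A \code{\link{cogmed_gain}} object or data frame with
#'   \code{subject_id} and \code{gain}.
#' @return Data frame with one row per slope column: \code{r}, \code{p},
#'   \code{neg_log10_p}, \code{n}.
#' @export
slope_gain_correlations <- function(slopes, gain) {
  if (inherits(gain, "cogmed_gain")) gain <- gain$scores
  d <- merge(slopes, gain, by = "subject_id")
  cols <- grep("^slope_", names(d), value = TRUE)
  do.call(rbind, lapply(cols, function(cl) {
    ok <- stats::complete.cases(d[[cl]], d$gain)
    ht <- stats::cor.test(d[[cl]][ok], d$gain[ok])
    data.frame(parameter = sub("^slope_", "", cl),
               r = unname(ht$estimate), p = ht$p.value,
               neg_log10_p = -log10(ht$p.value), n = sum(ok),
               stringsAsFactors = FALSE)
  }))
}

#' Mixed-effects session-by-arm models
#'
#' Per outcome, a linear mixed-effects model
#' outcome ~ session + age + sex + arm + session:arm with a subject-level
#' random intercept, fitted by REML. The t statistics use the model
#' standard errors; p values and confidence intervals use a t
#' distribution on the residual-df approximation (observations minus
#' fixed-effect count) -- an approximation, adequate for within-subject
#' contrasts at these panel sizes.
#'
#' @param sessions Long data frame with \code{subject_id}, \code{session},
#'   \code{arm}, \code{age}, \code{sex} and the outcomes; at least two
#'   sessions per subject.
#' @param outcomes Outcome column names.
#' @param conf_level Confidence level for the fixed-effect intervals.
#' @return List of class \code{"tva_lme"}: \code{fixed} (outcome, term,
#'   estimate, std_error, t, df, p, lower, upper) and \code{varcomp}
#'   (outcome, var_intercept, var_residual).
#' @export
lme_session_by_group <- function(sessions,
                                 outcomes = c("K", "C", "t0", "error_rate"),
                                 conf_level = 0.95) {
  ns <- tapply(sessions$session, sessions$subject_id,
               function(s) length(unique(s)))
  if (max(ns) < 2) stop("at least two sessions per subject are required")
  fixed <- list()
  varcomp <- list()
  for (oc in outcomes) {
    f <- stats::as.formula(paste(
      oc, "~ session + age + sex + arm + session:arm + (1 | subject_id)"))
    fit <- lme4::lmer(f, data = sessions, REML = TRUE)
    ct <- stats::coef(summary(fit))
    df <- nrow(sessions) - nrow(ct)
    q <- stats::qt(1 - (1 - conf_level) / 2, df)
    fixed[[oc]] <- data.frame(
      outcome = oc, term = rownames(ct), estimate = ct[, "Estimate"],
      std_error = ct[, "Std. Error"], t = ct[, "t value"], df = df,
      p = 2 * stats::pt(-abs(ct[, "t value"]), df),
      lower = ct[, "Estimate"] - q * ct[, "Std. Error"],
      upper = ct[, "Estimate"] + q * ct[, "Std. Error"],
      row.names = NULL, stringsAsFactors = FALSE)
    vc <- as.data.frame(lme4::VarCorr(fit))
    varcomp[[oc]] <- data.frame(
      outcome = oc,
      var_intercept = vc$vcov[vc$grp == "subject_id"][1],
      var_residual = vc$vcov[vc$grp == "Residual"][1],
      stringsAsFactors = FALSE)
  }
  structure(list(fixed = do.call(rbind, fixed),
                 varcomp = do.call(rbind, varcomp)),
            class = "tva_lme")
}

#' @export
print.tva_lme <- function(x, digits = 3, ...) {
  cat("Mixed-effects session-by-arm models\n")
  print(x$fixed, digits = digits, row.names = FALSE)
  invisible(x)
}
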