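#' Configuration for the case-control cohort generator
#'
#' Defaults emulate a chronic-stroke case-control study: 70 patients and
#' 140 age/sex-comparable controls (2:1), with additive group shifts on
#' the attention parameters of the magnitude seen in such cohorts
#' (patients: lower expected K and C, higher t0), linear age slopes, and a
#' sex effect on the perceptual threshold (men lower than women). Control
#' reference means are anchored at age \code{age_ref}.
#'
#' @param n_patients,n_controls Group sizes.
#' @param mean_K,mean_C,mean_t0,mean_error Control means at the reference
#'   age (letters, Hz, ms, proportion).
#' @param shift_K,shift_C,shift_t0,shift_error Additive patient-minus-
#'   control shifts.
#' @param age_slope_K,age_slope_C,age_slope_t0,age_slope_error Linear age
#'   effects per year.
#' @param sex_t0 Effect of male (vs female) on t0, ms.
#' @param sd_K,sd_C,sd_t0,sd_error Between-subject SDs of the latent
#'   parameters.
#' @param noise_K,noise_C,noise_t0,noise_error Measurement-noise SDs added
#'   to the latent values to emulate estimation error in the observed
#'   (fitted) outcomes.
#' @param age_range Uniform age range, years.
#' @param age_ref Reference age at which the control means apply.
#' @param prop_female_controls,prop_female_patients Sex composition.
#' @param seed Integer seed.
#' @return A list of class \code{"cohort_config"}.
#' @export
cohort_config <- function(n_patients = 70, n_controls = 140,
                          mean_K = 3.07, mean_C = 27.84, mean_t0 = 25.20,
                          mean_error = 0.11,
                          shift_K = -0.334, shift_C = -6.585,
                          shift_t0 = 7.828, shift_error = -0.021,
                          age_slope_K = -0.020, age_slope_C = -0.337,
                          age_slope_t0 = 0.407, age_slope_error = 0,
                          sex_t0 = -6.684,
                          sd_K = 0.60, sd_C = 12, sd_t0 = 13, sd_error = 0.07,
                          noise_K = 0.15, noise_C = 3, noise_t0 = 6,
                          noise_error = 0.02,
                          age_range = c(31, 81), age_ref = 67,
                          prop_female_controls = 0.393,
                          prop_female_patients = 0.286,
                          seed = 1L) {
  if (n_patients < 1 || n_controls < 1) stop("group sizes must be positive")
  sds <- c(sd_K, sd_C, sd_t0, sd_error, noise_K, noise_C, noise_t0,
           noise_error)
  if (any(sds < 0)) stop("SDs must be non-negative")
  if (mean_C + shift_C <= 0) {
    stop("patient mean C must remain positive; infeasible configuration")
  }
  structure(as.list(environment()), class = "cohort_config")
}

trunc_params <- function(K, C, t0, err, n) {
  data.frame(true_K = pmin(pmax(K, 1.01), n - 0.01),
             true_C = pmax(C, 1),
             true_t0 = pmax(t0, 0),
             true_error = pmin(pmax(err, 0), 0.5))
}

#' Generate a synthetic case-control cohort
#'
#' Draws subject covariates (age, sex, education, and for patients NIHSS,
#' stroke-subtype class, lesion location, training arm), latent attention
#' parameters from the additive group/age/sex structure of
#' \code{\link{cohort_config}} plus between-subject noise, and observed
#' outcomes as latent values plus measurement noise. Latent values are
#' truncated to their physical ranges (C > 0, t0 >= 0, expected K inside
#' its support). Optionally simulates full whole-report trial data per
#' subject so fits can be run end to end.
#'
#' @param config A \code{\link{cohort_config}}.
#' @param design A \code{\link{whole_report_design}} (used when
#'   \code{simulate_trials = TRUE}).
#' @param simulate_trials Also emit raw whole-report trials per subject
#'   (one session each) driven by the latent parameters.
#' @param seed Optional override of \code{config$seed}.
#' @return A list with \code{subjects} (covariates, latent \code{true_*}
#'   parameters, observed outcomes \code{K}, \code{C}, \code{t0},
#'   \code{error_rate}), \code{trials} (data frame or NULL) and
#'   \code{config}.
#' @export
generate_cohort <- function(config = cohort_config(),
                            design = whole_report_design(),
                            simulate_trials = FALSE, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  cf <- config
  n <- cf$n_patients + cf$n_controls
  with_seed(if (is.null(seed)) cf$seed else seed, {
    group <- factor(rep(c("control", "patient"),
                        c(cf$n_controls, cf$n_patients)),
                    levels = c("control", "patient"))
    patient <- as.numeric(group == "patient")
    age <- stats::runif(n, cf$age_range[1], cf$age_range[2])
    pf <- ifelse(patient == 1, cf$prop_female_patients,
                 cf$prop_female_controls)
    sex <- factor(ifelse(stats::runif(n) < pf, "female", "male"),
                  levels = c("female", "male"))
    male <- as.numeric(sex == "male")
    dage <- age - cf$age_ref
    lat <- trunc_params(
      cf$mean_K + cf$shift_K * patient + cf$age_slope_K * dage +
        stats::rnorm(n, 0, cf$sd_K),
      cf$mean_C + cf$shift_C * patient + cf$age_slope_C * dage +
        stats::rnorm(n, 0, cf$sd_C),
      cf$mean_t0 + cf$shift_t0 * patient + cf$age_slope_t0 * dage +
        cf$sex_t0 * male + stats::rnorm(n, 0, cf$sd_t0),
      cf$mean_error + cf$shift_error * patient +
        cf$age_slope_error * dage + stats::rnorm(n, 0, cf$sd_error),
      design$display_size)
    subjects <- data.frame(
      subject_id = sprintf("S%03d", seq_len(n)),
      group = group, age = age, sex = sex,
      education = pmax(stats::rnorm(n, 15.4, 3.4), 6),
      NIHSS = ifelse(patient == 1, stats::rbinom(n, 7, 0.19), NA),
      TOAST = ifelse(patient == 1,
                     sample(c("large_artery", "cardioembolism",
                              "small_vessel", "other"), n, replace = TRUE,
                            prob = c(23, 7, 21, 17)),
                     NA),
      lesion_location = ifelse(patient == 1,
                               sample(c("right", "left", "stem_cerebellum",
                                        "bilateral"), n, replace = TRUE,
                                      prob = c(30, 22, 9, 7)),
                               NA),
      arm = ifelse(patient == 1,
                   sample(c("sham", "active"), n, replace = TRUE), NA),
      stringsAsFactors = FALSE)
    subjects <- cbind(subjects, lat)
    subjects$K <- pmin(pmax(lat$true_K + stats::rnorm(n, 0, cf$noise_K),
                            1), design$display_size)
    subjects$C <- pmax(lat$true_C + stats::rnorm(n, 0, cf$noise_C), 0.5)
    subjects$t0 <- pmax(lat$true_t0 + stats::rnorm(n, 0, cf$noise_t0), 0)
    subjects$error_rate <- pmin(pmax(lat$true_error +
                                       stats::rnorm(n, 0, cf$noise_error),
                                     0), 1)
    trials <- NULL
    if (simulate_trials) {
      trials <- do.call(rbind, lapply(seq_len(n), function(i) {
        par <- tva_par(k_dist_from_mean(lat$true_K[i], design$display_size),
                       lat$true_C[i], lat$true_t0[i], mu = 90)
        simulate_session(par, design, guess_rate = lat$true_error[i],
                         subject_id = subjects$subject_id[i])
      }))
    }
    list(subjects = subjects, trials = trials, config = cf)
  })
}

#' Configuration for the repeated-session (reliability) generator
#'
#' Defaults emulate six weekly whole-report assessments during a
#' three-week computerised training programme in 54 patients: linear
#' practice trends per session on every parameter, subject-level random
#' intercepts sized to target the intended intraclass correlations (via
#' within-session noise \code{sd_w = sd_b * sqrt((1 - icc) / icc)}),
#' subject-level random slopes, and a sham/active arm split with zero
#' true arm effect.
#'
#' @param n_subjects,n_sessions Panel dimensions (sessions coded 1..S).
#' @param mean_K,mean_C,mean_t0,mean_error Session-1 population means.
#' @param trend_K,trend_C,trend_t0,trend_error Linear change per session.
#' @param icc_K,icc_C,icc_t0,icc_error Target intraclass correlations of
#'   the latent per-session values (between-subject variance share).
#' @param sd_b_K,sd_b_C,sd_b_t0,sd_b_error Between-subject intercept SDs.
#' @param slope_sd_K,slope_sd_C,slope_sd_t0,slope_sd_error Subject-level
#'   SDs of the session trend (individual practice-gain differences).
#' @param arm_trend_K,arm_trend_C,arm_trend_t0,arm_trend_error Additional
#'   per-session trend in the active arm (zero: no true stimulation
#'   effect).
#' @param age_mean,age_sd,prop_female Covariate structure.
#' @param seed Integer seed.
#' @return A list of class \code{"longitudinal_config"}.
#' @export
longitudinal_config <- function(n_subjects = 54, n_sessions = 6,
                                mean_K = 2.8, mean_C = 22, mean_t0 = 30,
                                mean_error = 0.09,
                                trend_K = 0.090, trend_C = 2.004,
                                trend_t0 = -2.502, trend_error = 0.006,
                                icc_K = 0.80, icc_C = 0.72, icc_t0 = 0.58,
                                icc_error = 0.65,
                                sd_b_K = 0.74, sd_b_C = 11, sd_b_t0 = 16,
                                sd_b_error = 0.07,
                                slope_sd_K = 0.06, slope_sd_C = 0.9,
                                slope_sd_t0 = 1.2, slope_sd_error = 0.004,
                                arm_trend_K = 0, arm_trend_C = 0,
                                arm_trend_t0 = 0, arm_trend_error = 0,
                                age_mean = 69.7, age_sd = 7.5,
                                prop_female = 0.26, seed = 1L) {
  if (n_sessions < 2) stop("n_sessions must be >= 2")
  iccs <- c(icc_K, icc_C, icc_t0, icc_error)
  if (any(iccs <= 0 | iccs >= 1)) stop("target ICCs must lie in (0, 1)")
  structure(as.list(environment()), class = "longitudinal_config")
}

#' Generate a synthetic repeated-session panel
#'
#' Each subject receives a latent intercept per parameter (between-subject
#' SD from the config), a subject-specific linear session trend, and
#' within-session noise sized so the latent values attain the target
#' intraclass correlations. Observed outcomes per session are the latent
#' values truncated to physical ranges. The true ICC of the latent
#' stationary component is sd_b^2 / (sd_b^2 + sd_w^2) by construction;
#' estimates from fitted or noisy data fall below the target through
#' measurement-error attenuation and practice trends.
#'
#' @param config A \code{\link{longitudinal_config}}.
#' @param design A \code{\link{whole_report_design}} (for
#'   \code{simulate_trials}).
#' @param simulate_trials Also emit raw trials per subject-session.
#' @param seed Optional override of \code{config$seed}.
#' @return A list with \code{sessions} (long data frame: one row per
#'   subject x session with covariates and outcomes \code{K}, \code{C},
#'   \code{t0}, \code{error_rate}), \code{subjects} (per-subject latent
#'   intercept and slope deviations \code{dev_*}), \code{trials} and
#'   \code{config}.
#' @export
generate_longitudinal <- function(config = longitudinal_config(),
                                  design = whole_report_design(),
                                  simulate_trials = FALSE, seed = NULL) {
  stopifnot(inherits(config, "longitudinal_config"))
  cf <- config
  n <- cf$n_subjects
  S <- cf$n_sessions
  with_seed(if (is.null(seed)) cf$seed else seed, {
    pars <- c("K", "C", "t0", "error")
    sd_b <- c(cf$sd_b_K, cf$sd_b_C, cf$sd_b_t0, cf$sd_b_error)
    icc <- c(cf$icc_K, cf$icc_C, cf$icc_t0, cf$icc_error)
    sd_w <- sd_b * sqrt((1 - icc) / icc)
    mean0 <- c(cf$mean_K, cf$mean_C, cf$mean_t0, cf$mean_error)
    trend <- c(cf$trend_K, cf$trend_C, cf$trend_t0, cf$trend_error)
    slope_sd <- c(cf$slope_sd_K, cf$slope_sd_C, cf$slope_sd_t0,
                  cf$slope_sd_error)
    arm_tr <- c(cf$arm_trend_K, cf$arm_trend_C, cf$arm_trend_t0,
                cf$arm_trend_error)
    arm <- factor(sample(rep(c("sham", "active"), length.out = n)),
                  levels = c("sham", "active"))
    subjects <- data.frame(
      subject_id = sprintf("P%03d", seq_len(n)), arm = arm,
      age = stats::rnorm(n, cf$age_mean, cf$age_sd),
      sex = factor(ifelse(stats::runif(n) < cf$prop_female,
                          "female", "male"), levels = c("female", "male")),
      stringsAsFactors = FALSE)
    for (j in seq_along(pars)) {
      subjects[[paste0("int_", pars[j])]] <- stats::rnorm(n, 0, sd_b[j])
      subjects[[paste0("dev_", pars[j])]] <- stats::rnorm(n, 0, slope_sd[j])
    }
    active <- as.numeric(arm == "active")
    long <- do.call(rbind, lapply(seq_len(S), function(s) {
      d <- subjects[, c("subject_id", "arm", "age", "sex")]
      d$session <- s
      lat <- sapply(seq_along(pars), function(j) {
        mean0[j] + subjects[[paste0("int_", pars[j])]] +
          (trend[j] + subjects[[paste0("dev_", pars[j])]] +
             arm_tr[j] * active) * (s - 1) +
          stats::rnorm(n, 0, sd_w[j])
      })
      tp <- trunc_params(lat[, 1], lat[, 2], lat[, 3], lat[, 4],
                         design$display_size)
      d$K <- tp$true_K
      d$C <- tp$true_C
      d$t0 <- tp$true_t0
      d$error_rate <- tp$true_error
      d
    }))
    long <- long[order(long$subject_id, long$session), ]
    rownames(long) <- NULL
    trials <- NULL
    if (simulate_trials) {
      trials <- do.call(rbind, lapply(seq_len(nrow(long)), function(i) {
        par <- tva_par(k_dist_from_mean(long$K[i], design$display_size),
                       long$C[i], long$t0[i], mu = 90)
        simulate_session(par, design, guess_rate = long$error_rate[i],
                         subject_id = long$subject_id[i],
                         session = long$session[i])
      }))
    }
    list(sessions = long, subjects = subjects, trials = trials, config = cf)
  })
}

#' Configuration for the training-curve generator
#'
#' Emulates a computerised working-memory training programme: 10 distinct
#' tasks trained over 17 sessions, with a subject-level latent gain factor
#' loading on every task's per-session improvement slope. The latent gain
#' can be coupled to subject-level attention-parameter practice slopes
#' (from \code{\link{generate_longitudinal}}), reproducing the observed
#' pattern of training gain correlating positively with capacity change,
#' negatively with threshold change and not with speed change.
#'
#' @param n_tasks,n_sessions Panel dimensions.
#' @param gain_sd SD of the latent gain factor.
#' @param loadings Per-task loadings on the latent gain (recycled to
#'   \code{n_tasks}).
#' @param base_slope Common per-session improvement independent of gain.
#' @param intercept_mean,intercept_sd Task starting-level distribution.
#' @param residual_sd Session-level performance noise.
#' @param coupling Named numeric: weights of the standardised subject
#'   slope deviations (\code{K}, \code{C}, \code{t0}, \code{error_rate})
#'   in the latent gain when a longitudinal panel is supplied.
#' @param coupling_noise_sd Residual SD of the latent gain around the
#'   coupled component.
#' @param seed Integer seed.
#' @return A list of class \code{"cogmed_config"}.
#' @export
cogmed_config <- function(n_tasks = 10, n_sessions = 17, gain_sd = 1,
                          loadings = seq(0.6, 1, length.out = n_tasks),
                          base_slope = 0.5,
                          intercept_mean = 20, intercept_sd = 5,
                          residual_sd = 2,
                          coupling = c(K = 0.6, C = 0, t0 = -0.4,
                                       error_rate = 0.3),
                          coupling_noise_sd = 0.6, seed = 1L) {
  if (n_tasks < 1 || n_sessions < 2) stop("invalid panel dimensions")
  if (gain_sd < 0 || residual_sd < 0) stop("SDs must be non-negative")
  loadings <- rep_len(loadings, n_tasks)
  structure(as.list(environment()), class = "cogmed_config")
}

#' Generate synthetic training-performance trajectories
#'
#' Per subject and task, performance follows
#' intercept + (base_slope + loading x gain) x (session - 1) + noise.
#' The latent gain is either drawn independently (\code{gain_sd}) or, when
#' a longitudinal panel is supplied, built from the subjects' standardised
#' attention-parameter slope deviations using the config's coupling
#' weights plus residual noise.
#'
#' @param config A \code{\link{cogmed_config}}.
#' @param n_subjects Number of subjects (ignored when \code{longitudinal}
#'   supplies them).
#' @param longitudinal Optional result of
#'   \code{\link{generate_longitudinal}}; couples the latent gain to its
#'   subjects' practice slopes.
#' @param seed Optional override of \code{config$seed}.
#' @return A list with \code{performance} (long data frame: subject_id,
#'   task, session, performance), \code{subjects} (with the latent
#'   \code{gain}) and \code{config}.
#' @export
generate_cogmed <- function(config = cogmed_config(), n_subjects = 54,
                            longitudinal = NULL, seed = NULL) {
  stopifnot(inherits(config, "cogmed_config"))
  cf <- config
  with_seed(if (is.null(seed)) cf$seed else seed, {
    if (!is.null(longitudinal)) {
      sub <- longitudinal$subjects
      ids <- sub$subject_id
      n <- length(ids)
      devs <- cbind(K = sub$dev_K, C = sub$dev_C, t0 = sub$dev_t0,
                    error_rate = sub$dev_error)
      z <- scale(devs)
      z[is.nan(z)] <- 0
      w <- cf$coupling[colnames(z)]
      w[is.na(w)] <- 0
      gain <- as.vector(z %*% w) +
        stats::rnorm(n, 0, cf$coupling_noise_sd)
    } else {
      n <- n_subjects
      ids <- sprintf("P%03d", seq_len(n))
      gain <- stats::rnorm(n, 0, cf$gain_sd)
    }
    intercepts <- stats::rnorm(cf$n_tasks, cf$intercept_mean,
                               cf$intercept_sd)
    grid <- expand.grid(subject = seq_len(n), task = seq_len(cf$n_tasks),
                        session = seq_len(cf$n_sessions))
    perf <- intercepts[grid$task] +
      (cf$base_slope + cf$loadings[grid$task] * gain[grid$subject]) *
        (grid$session - 1) +
      stats::rnorm(nrow(grid), 0, cf$residual_sd)
    performance <- data.frame(
      subject_id = ids[grid$subject],
      task = paste0("task", grid$task),
      session = grid$session,
      performance = perf, stringsAsFactors = FALSE)
    performance <- performance[order(performance$subject_id,
                                     performance$task,
                                     performance$session), ]
    rownames(performance) <- NULL
    list(performance = performance,
         subjects = data.frame(subject_id = ids, gain = gain,
                               stringsAsFactors = FALSE),
         config = cf)
  })
}
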