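#' Simulate correct-report scores from the race process
#'
#' Vectorised race simulator: for each trial a capacity k is drawn from
#' the capacity distribution, each displayed letter races with an
#' independent exponential finishing time at rate C / display_size per
#' second, letters finishing within the effective exposure are encoded,
#' and the score is the number encoded truncated to the k fastest. This
#' is the generating mechanism whose marginal distribution
#' \code{\link{score_mixture_pmf}} states in closed form, so it serves as
#' the Monte-Carlo oracle for the model.
#'
#' @param params A \code{\link{tva_par}}.
#' @param exposure_ms Nominal exposure, ms.
#' @param masked Logical mask flag.
#' @param design A \code{\link{whole_report_design}}.
#' @param n_trials Number of trials to simulate.
#' @return Integer vector of scores in 0..display_size.
#' @export
simulate_scores <- function(params, exposure_ms, masked, design, n_trials) {
  stopifnot(inherits(params, "tva_par"), inherits(design, "wr_design"))
  n <- design$display_size
  tau <- effective_exposure(exposure_ms, masked, params$t0, params$mu) / 1000
  v <- params$C / n
  k <- sample.int(n, n_trials, replace = TRUE, prob = params$k_dist)
  times <- matrix(stats::rexp(n_trials * n, rate = v), n_trials, n)
  encoded <- rowSums(times <= tau)
  as.integer(pmin(encoded, k))
}

#' Simulate a single whole-report trial
#'
#' Draws one trial from the race process: a display of distinct letters,
#' a capacity k from the capacity distribution, exponential per-letter
#' finishing times, and a report consisting of the (at most k) letters
#' encoded within the effective exposure, optionally contaminated by one
#' guessed intrusion letter (a symbol not in the display) with probability
#' \code{guess_rate}.
#'
#' @param params A \code{\link{tva_par}}.
#' @param exposure_ms Nominal exposure, ms.
#' @param masked Logical mask flag.
#' @param design A \code{\link{whole_report_design}}.
#' @param guess_rate Per-trial intrusion probability in [0, 1).
#' @param subject_id,session,trial_index,is_practice Bookkeeping fields.
#' @return One-row data frame with the trial record fields
#'   (\code{subject_id}, \code{session}, \code{trial_index},
#'   \code{exposure_ms}, \code{masked}, \code{displayed}, \code{reported},
#'   \code{is_practice}, \code{score}).
#' @export
simulate_trial <- function(params, exposure_ms, masked, design,
                           guess_rate = 0, subject_id = "s1", session = 1L,
                           trial_index = 1L, is_practice = FALSE) {
  stopifnot(inherits(params, "tva_par"), inherits(design, "wr_design"))
  if (guess_rate < 0 || guess_rate >= 1) stop("guess_rate must lie in [0, 1)")
  n <- design$display_size
  tau <- effective_exposure(exposure_ms, masked, params$t0, params$mu) / 1000
  displayed <- sample(design$letter_set, n)
  k <- sample.int(n, 1, prob = params$k_dist)
  times <- stats::rexp(n, rate = params$C / n)
  finished <- which(times <= tau)
  if (length(finished) > k) {
    finished <- finished[order(times[finished])][seq_len(k)]
  }
  reported <- displayed[sort(finished)]
  if (guess_rate > 0 && stats::runif(1) < guess_rate) {
    pool <- setdiff(design$letter_set, displayed)
    if (length(pool) > 0) reported <- c(reported, sample(pool, 1))
  }
  data.frame(subject_id = subject_id, session = as.integer(session),
             trial_index = as.integer(trial_index),
             exposure_ms = exposure_ms, masked = as.logical(masked),
             displayed = paste(displayed, collapse = ""),
             reported = paste(reported, collapse = ""),
             is_practice = as.logical(is_practice),
             score = length(finished),
             stringsAsFactors = FALSE)
}

#' Simulate a whole-report session
#'
#' Emits the practice trials followed by the test trials of one session,
#' with the test conditions repeated \code{trials_per_condition} times
#' each in randomised order (the default design gives 20 practice plus
#' 140 test trials over 7 conditions). Practice trials draw their
#' condition at random from the ladder and are flagged
#' \code{is_practice}.
#'
#' @param params A \code{\link{tva_par}}.
#' @param design A \code{\link{whole_report_design}}.
#' @param guess_rate Per-trial intrusion probability.
#' @param subject_id,session Bookkeeping fields stamped on every row.
#' @param seed Optional integer seed (restores the caller's RNG state).
#' @return Data frame of trial records, one row per trial.
#' @export
simulate_session <- function(params, design, guess_rate = 0,
                             subject_id = "s1", session = 1L, seed = NULL) {
  with_seed(seed, {
    conds <- design_conditions(design)
    n_test <- nrow(conds) * design$trials_per_condition
    order_test <- sample(rep(seq_len(nrow(conds)), design$trials_per_condition))
    prac_cond <- sample(seq_len(nrow(conds)), design$practice_trials,
                        replace = TRUE)
    idx <- c(prac_cond, order_test)
    practice <- c(rep(TRUE, design$practice_trials), rep(FALSE, n_test))
    rows <- lapply(seq_along(idx), function(i) {
      simulate_trial(params, conds$exposure_ms[idx[i]], conds$masked[idx[i]],
                     design, guess_rate = guess_rate,
                     subject_id = subject_id, session = session,
                     trial_index = i, is_practice = practice[i])
    })
    do.call(rbind, rows)
  })
}
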