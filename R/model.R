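#' Effective exposure duration
#'
#' The exposure time actually available for visual encoding. Masked
#' displays yield the nominal exposure minus the perceptual threshold t0;
#' unmasked displays additionally gain mu ms of effective exposure from
#' iconic persistence after stimulus offset. Negative values truncate to 0.
#'
#' @param exposure_ms Nominal exposure duration in ms (> 0). Vectorised.
#' @param masked Logical; was the display terminated by a pattern mask?
#' @param t0 Perceptual threshold in ms (may be negative during
#'   unconstrained fitting).
#' @param mu Additional effective exposure for unmasked displays, ms.
#' @return Effective exposure in ms, >= 0.
#' @examples
#' effective_exposure(200, TRUE, t0 = 200, mu = 0)    # 0
#' effective_exposure(40, FALSE, t0 = 20, mu = 100)   # 120
#' @export
effective_exposure <- function(exposure_ms, masked, t0, mu) {
  pmax(0, exposure_ms - t0 + ifelse(masked, 0, mu))
}

#' Per-letter encoding probability
#'
#' In whole report with homogeneous targets each of the display_size
#' letters races with equal rate v = C / display_size (per second). The
#' probability that a given letter finishes within the effective exposure
#' tau (ms) is 1 - exp(-v * tau / 1000).
#'
#' @param C Total processing rate in Hz; must be positive.
#' @param tau_eff Effective exposure in ms, >= 0. Vectorised.
#' @param display_size Number of display items sharing the rate.
#' @return Encoding probability in [0, 1); 0 exactly when tau_eff is 0.
#' @examples
#' encoding_probability(30, 200, 6)   # 1 - exp(-1)
#' @export
encoding_probability <- function(C, tau_eff, display_size) {
  if (!all(is.finite(C)) || any(C <= 0)) stop("C must be positive")
  if (any(tau_eff < 0)) stop("tau_eff must be >= 0")
  -expm1(-(C / display_size) * tau_eff / 1000)
}

#' Score distribution for a fixed capacity
#'
#' Distribution of the number of correctly reported letters given that
#' capacity on this trial is k. Each of the n displayed letters is encoded
#' independently with probability p; only the k fastest can be stored, so
#' the binomial count is truncated at k with the upper tail collapsed onto
#' k: P(m) = dbinom(m, n, p) for m < k, P(k) = sum of the binomial tail
#' from k to n, and P(m) = 0 for m > k.
#'
#' @param p Per-letter encoding probability in [0, 1].
#' @param k Capacity on this trial, in 1..display_size.
#' @param display_size Number of display items n.
#' @return Probability vector over scores 0..display_size (sums to 1).
#' @examples
#' score_pmf(0.5, 2, 6) * 64   # 1, 6, 57, 0, 0, 0, 0
#' @export
score_pmf <- function(p, k, display_size) {
  if (p < 0 || p > 1) stop("p must lie in [0, 1]")
  k <- as.integer(k)
  if (k < 1L || k > display_size) stop("k must lie in 1..display_size")
  pmf <- numeric(display_size + 1)
  m <- 0:display_size
  if (k == display_size) return(stats::dbinom(m, display_size, p))
  pmf[1:k] <- stats::dbinom(0:(k - 1), display_size, p)
  pmf[k + 1] <- stats::pbinom(k - 1, display_size, p, lower.tail = FALSE)
  pmf
}

#' Score distribution under the capacity mixture
#'
#' Marginal distribution of the correct-report score in one exposure
#' condition: the capacity-conditional score distributions averaged over
#' the capacity distribution P(K = k), with the encoding probability
#' computed from C, t0 and mu through the effective exposure.
#'
#' @param params A \code{\link{tva_par}} object.
#' @param exposure_ms Nominal exposure in ms.
#' @param masked Logical mask flag.
#' @param design A \code{\link{whole_report_design}}.
#' @return Probability vector over scores 0..display_size.
#' @export
score_mixture_pmf <- function(params, exposure_ms, masked, design) {
  stopifnot(inherits(params, "tva_par"), inherits(design, "wr_design"))
  n <- design$display_size
  tau <- effective_exposure(exposure_ms, masked, params$t0, params$mu)
  p <- encoding_probability(params$C, tau, n)
  mixture_pmf(params$k_dist, p, n)
}

# Closed form of sum_k pi_k * score_pmf(p, k, n): a score of m arises from
# capacities k > m via the plain binomial term and from k = m via the
# collapsed binomial tail. O(n) per evaluation.
mixture_pmf <- function(k_dist, p, n) {
  db <- stats::dbinom(0:n, n, p)
  tail_ge <- rev(cumsum(rev(db)))         # T(m) = P(Binom >= m)
  surv <- rev(cumsum(rev(k_dist)))        # P(K >= k), k = 1..n
  pmf <- numeric(n + 1)
  pmf[1] <- db[1]                         # every capacity admits score 0
  m <- 1:n
  p_gt <- c(surv[-1], 0)                  # P(K > m)
  pmf[m + 1] <- db[m + 1] * p_gt + k_dist[m] * tail_ge[m + 1]
  pmf
}

#' Tabulate correct-report scores by condition
#'
#' Reduces raw trials to the sufficient statistic of the equal-weight
#' whole-report likelihood: for every (exposure, masked) condition, the
#' counts of trials that scored m = 0..display_size correctly reported
#' letters. Practice trials are dropped.
#'
#' @param trials Data frame of trials as produced by
#'   \code{\link{simulate_session}} or \code{\link{read_trials}}, with
#'   columns \code{exposure_ms}, \code{masked}, \code{is_practice} and
#'   either \code{score} or \code{displayed}/\code{reported} strings.
#' @param design A \code{\link{whole_report_design}}; conditions absent
#'   from the data appear with zero counts.
#' @return A \code{"score_table"}: integer matrix with one row per
#'   condition and columns for scores 0..display_size, with a
#'   \code{conditions} attribute data frame.
#' @export
score_table <- function(trials, design) {
  stopifnot(inherits(design, "wr_design"))
  n <- design$display_size
  conds <- design_conditions(design)
  trials <- trials[!as.logical(trials$is_practice), , drop = FALSE]
  if (nrow(trials) == 0) stop("no non-practice trials to tabulate")
  sc <- trial_scores(trials)
  if (any(sc > n)) stop("trial score exceeds display_size")
  counts <- matrix(0L, nrow(conds), n + 1,
                   dimnames = list(NULL, paste0("score", 0:n)))
  key <- paste(conds$exposure_ms, conds$masked)
  tkey <- paste(trials$exposure_ms, as.logical(trials$masked))
  unknown <- !(tkey %in% key)
  if (any(unknown)) {
    stop("trials contain conditions absent from the design: ",
         paste(unique(tkey[unknown]), collapse = "; "))
  }
  for (i in seq_len(nrow(conds))) {
    counts[i, ] <- tabulate(sc[tkey == key[i]] + 1L, nbins = n + 1)
  }
  structure(counts, conditions = conds, class = c("score_table", "matrix"))
}

#' Build a score table directly from counts
#'
#' @param counts Matrix of score counts, one row per condition, columns
#'   scores 0..display_size.
#' @param conditions Data frame with \code{exposure_ms} and \code{masked},
#'   one row per row of \code{counts}.
#' @return A \code{"score_table"}.
#' @export
score_table_from_counts <- function(counts, conditions) {
  counts <- as.matrix(counts)
  if (nrow(counts) != nrow(conditions)) {
    stop("counts and conditions must have matching rows")
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  colnames(counts) <- paste0("score", seq_len(ncol(counts)) - 1)
  structure(counts,
            conditions = data.frame(exposure_ms = conditions$exposure_ms,
                                    masked = as.logical(conditions$masked)),
            class = c("score_table", "matrix"))
}

#' Per-trial correct-report scores
#'
#' @param trials Trial data frame; uses a \code{score} column when present,
#'   otherwise counts distinct reported symbols present in the display.
#' @return Integer vector of scores.
#' @export
trial_scores <- function(trials) {
  if (!is.null(trials$score)) return(as.integer(trials$score))
  mapply(function(d, r) {
    if (is.na(r) || !nzchar(r)) return(0L)
    length(intersect(unique(strsplit(r, "")[[1]]), strsplit(d, "")[[1]]))
  }, trials$displayed, trials$reported, USE.NAMES = FALSE)
}

#' Whole-report session log-likelihood
#'
#' Multinomial log-likelihood of a score table under the capacity-mixture
#' race model: the sum over conditions and scores of count * log(model
#' probability). An observed score with zero model probability (for
#' example a score above the largest capacity with positive mass) yields
#' -Inf.
#'
#' @param params A \code{\link{tva_par}} object.
#' @param scores A \code{\link{score_table}}.
#' @param design The matching \code{\link{whole_report_design}}.
#' @return Log-likelihood (may be -Inf).
#' @export
session_loglik <- function(params, scores, design) {
  stopifnot(inherits(scores, "score_table"))
  conds <- attr(scores, "conditions")
  dc <- design_conditions(design)
  if (!all(paste(conds$exposure_ms, conds$masked) %in%
             paste(dc$exposure_ms, dc$masked))) {
    stop("score table conditions do not match the design")
  }
  ll <- 0
  for (i in seq_len(nrow(conds))) {
    pmf <- score_mixture_pmf(params, conds$exposure_ms[i], conds$masked[i],
                             design)
    obs <- scores[i, ] > 0
    if (any(obs & pmf <= 0)) return(-Inf)
    ll <- ll + sum(scores[i, obs] * log(pmf[obs]))
  }
  ll
}

#' Intrusion error rate of a session
#'
#' Fraction of reported letters that were not present in that trial's
#' display, pooled over the non-practice trials of one session. When no
#' letters were reported at all the rate is 0 and the result carries
#' attribute \code{no_reports = TRUE} (with a warning).
#'
#' @param trials Trial data frame with \code{displayed} and \code{reported}
#'   strings and an \code{is_practice} flag.
#' @return Error rate in [0, 1].
#' @export
error_rate <- function(trials) {
  if (is.null(trials) || nrow(trials) == 0) stop("empty trial list")
  trials <- trials[!as.logical(trials$is_practice), , drop = FALSE]
  if (nrow(trials) == 0) stop("no non-practice trials")
  reported <- 0L
  wrong <- 0L
  for (i in seq_len(nrow(trials))) {
    r <- trials$reported[i]
    if (is.na(r) || !nzchar(r)) next
    rs <- strsplit(r, "")[[1]]
    ds <- strsplit(trials$displayed[i], "")[[1]]
    reported <- reported + length(rs)
    wrong <- wrong + sum(!(rs %in% ds))
  }
  if (reported == 0L) {
    warning("no letters reported in the entire session; error rate set to 0")
    return(structure(0, no_reports = TRUE))
  }
  wrong / reported
}
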