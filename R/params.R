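#' TVA parameter set for the whole-report race model
#'
#' Bundles the model state: a probability distribution over short-term
#' memory capacity K (support 1..display_size), total processing speed C
#' in Hz (letters/second, shared equally across display items), perceptual
#' threshold t0 in ms, and the additional effective exposure mu in ms for
#' unmasked displays. With a display of 6 the capacity distribution holds
#' 5 free degrees of freedom, and C, t0, mu one each: 8 df in total.
#'
#' @param k_dist Probability vector over K = 1..display_size. Must be
#'   non-negative and sum to 1 (tolerance 1e-9).
#' @param C Total processing rate in Hz; must be positive.
#' @param t0 Perceptual threshold in ms. May be negative only during
#'   unconstrained fitting; a finished fit reports t0 >= 0.
#' @param mu Additional effective exposure for unmasked displays, ms, >= 0.
#'
#' @return An object of class \code{"tva_par"} with fields \code{k_dist},
#'   \code{C}, \code{t0}, \code{mu} and the derived \code{expected_K}.
#' @examples
#' p <- tva_par(k_dist = c(0, 0, .2, .6, .2, 0), C = 22, t0 = 30, mu = 90)
#' p$expected_K   # 4
#' @export
tva_par <- function(k_dist, C, t0 = 0, mu = 0) {
  k_dist <- as.numeric(k_dist)
  if (length(k_dist) < 1L) stop("k_dist must be non-empty")
  if (any(k_dist < -1e-12)) stop("k_dist entries must be non-negative")
  if (abs(sum(k_dist) - 1) > 1e-9) stop("k_dist must sum to 1 (tolerance 1e-9)")
  k_dist <- pmax(k_dist, 0)
  k_dist <- k_dist / sum(k_dist)
  if (!is.finite(C) || C <= 0) stop("C must be a positive processing rate (Hz)")
  if (!is.finite(t0)) stop("t0 must be finite")
  if (!is.finite(mu) || mu < 0) stop("mu must be >= 0")
  structure(
    list(k_dist = k_dist, C = C, t0 = t0, mu = mu,
         expected_K = expected_K(k_dist)),
    class = "tva_par")
}

#' Expected short-term memory capacity
#'
#' The expectation of the capacity distribution: sum of k * P(K = k)
#' over the support 1..length(k_dist).
#'
#' @param k_dist Probability vector over K = 1..length(k_dist).
#' @return Expected K in letters.
#' @examples
#' expected_K(rep(1 / 6, 6))             # 3.5
#' expected_K(c(0, 0, .2, .6, .2, 0))    # 4
#' @export
expected_K <- function(k_dist) {
  if (inherits(k_dist, "tva_par")) k_dist <- k_dist$k_dist
  k_dist <- as.numeric(k_dist)
  if (any(!is.finite(k_dist)) || any(k_dist < -1e-12) ||
      abs(sum(k_dist) - 1) > 1e-9) {
    stop("k_dist must be a probability vector summing to 1")
  }
  sum(seq_along(k_dist) * k_dist)
}

#' Capacity distribution with a given mean
#'
#' Maps a target expected capacity onto a full distribution over
#' K = 1..display_size by placing K - 1 on a Binomial(display_size - 1, q)
#' with q chosen so the mean matches. Used by the synthetic cohort
#' generators, which draw subject-level expected K and need a complete
#' distribution to run the race simulator.
#'
#' @param ek Target expected K, in [1, display_size].
#' @param display_size Number of display items (support upper end).
#' @return Probability vector over 1..display_size with mean \code{ek}.
#' @export
k_dist_from_mean <- function(ek, display_size = 6) {
  if (ek < 1 || ek > display_size) stop("ek must lie in [1, display_size]")
  stats::dbinom(0:(display_size - 1), display_size - 1,
                (ek - 1) / (display_size - 1))
}

#' @export
print.tva_par <- function(x, digits = 3, ...) {
  cat("TVA parameters\n")
  cat("  expected K:", format(x$expected_K, digits = digits), "letters\n")
  cat("  C: ", format(x$C, digits = digits), " Hz   t0: ",
      format(x$t0, digits = digits), " ms   mu: ",
      format(x$mu, digits = digits), " ms\n", sep = "")
  cat("  P(K = k):", paste(format(x$k_dist, digits = digits), collapse = " "), "\n")
  invisible(x)
}
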