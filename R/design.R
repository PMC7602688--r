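#' Whole-report experiment design
#'
#' Describes the structure of a whole-report session: how many letters are
#' shown at once, the ladder of exposure durations (masked and unmasked),
#' how many trials each condition receives, and the letter alphabet.
#' The defaults reproduce the standard clinical protocol: six letters drawn
#' from a 20-letter alphabet, masked exposures of 20, 40, 60, 110 and 200 ms,
#' unmasked exposures of 40 and 200 ms, 20 test trials per condition
#' (140 test trials) preceded by 20 practice trials.
#'
#' @param display_size Number of letters shown simultaneously.
#' @param masked_exposures Exposure durations (ms) terminated by a pattern
#'   mask.
#' @param unmasked_exposures Exposure durations (ms) without a mask; these
#'   receive the additional effective exposure \code{mu}.
#' @param trials_per_condition Test trials per exposure condition.
#' @param letter_set Character vector of distinct stimulus symbols.
#' @param practice_trials Number of practice trials (always excluded from
#'   fitting).
#'
#' @return An object of class \code{"wr_design"}.
#' @examples
#' d <- whole_report_design()
#' d$display_size
#' nrow(design_conditions(d))
#' @export
whole_report_design <- function(display_size = 6,
                                masked_exposures = c(20, 40, 60, 110, 200),
                                unmasked_exposures = c(40, 200),
                                trials_per_condition = 20,
                                letter_set = strsplit("ABDEFGHJKLMNOPRSTVXZ", "")[[1]],
                                practice_trials = 20) {
  display_size <- as.integer(display_size)
  letter_set <- as.character(letter_set)
  if (display_size < 1L) stop("display_size must be >= 1")
  if (any(c(masked_exposures, unmasked_exposures) <= 0)) {
    stop("all exposure durations must be positive")
  }
  if (anyDuplicated(letter_set)) stop("letter_set must contain distinct symbols")
  if (length(letter_set) < display_size) {
    stop("letter_set must contain at least display_size symbols")
  }
  if (trials_per_condition < 1L) stop("trials_per_condition must be >= 1")
  structure(
    list(display_size = display_size,
         masked_exposures = as.numeric(masked_exposures),
         unmasked_exposures = as.numeric(unmasked_exposures),
         trials_per_condition = as.integer(trials_per_condition),
         letter_set = letter_set,
         practice_trials = as.integer(practice_trials)),
    class = "wr_design")
}

#' Condition table of a design
#'
#' @param design A \code{"wr_design"} object.
#' @return A data frame with one row per exposure condition and columns
#'   \code{exposure_ms} and \code{masked}.
#' @export
design_conditions <- function(design) {
  stopifnot(inherits(design, "wr_design"))
  data.frame(
    exposure_ms = c(design$masked_exposures, design$unmasked_exposures),
    masked = c(rep(TRUE, length(design$masked_exposures)),
               rep(FALSE, length(design$unmasked_exposures))))
}

#' @export
print.wr_design <- function(x, ...) {
  cat("Whole-report design\n")
  cat("  display size: ", x$display_size, " letters from {",
      paste(x$letter_set, collapse = ""), "}\n", sep = "")
  cat("  masked exposures (ms):  ", paste(x$masked_exposures, collapse = ", "), "\n")
  cat("  unmasked exposures (ms):", paste(x$unmasked_exposures, collapse = ", "), "\n")
  cat("  trials/condition:", x$trials_per_condition,
      " practice trials:", x$practice_trials, "\n")
  invisible(x)
}
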