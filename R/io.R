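#' Read whole-report trials from CSV
#'
#' One row per trial with columns \code{subject_id}, \code{session},
#' \code{trial_index}, \code{exposure_ms}, \code{masked} (0/1),
#' \code{displayed} (concatenated uppercase symbols), \code{reported}
#' (concatenated symbols, empty allowed) and \code{is_practice} (0/1).
#' Each row is validated: displayed letters must be distinct,
#' display-sized and drawn from the design's alphabet, and the
#' correct-report score cannot exceed the display size. Malformed rows
#' are reported with their line numbers.
#'
#' @param path CSV file path.
#' @param design A \code{\link{whole_report_design}} used for validation.
#' @return Trial data frame with a computed \code{score} column.
#' @export
read_trials <- function(path, design = whole_report_design()) {
  if (!file.exists(path)) stop("trial file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(displayed = "character",
                                      reported = "character"))
  need <- c("subject_id", "session", "trial_index", "exposure_ms",
            "masked", "displayed", "reported", "is_practice")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  d$masked <- as.logical(d$masked)
  d$is_practice <- as.logical(d$is_practice)
  d$reported[is.na(d$reported)] <- ""
  probs <- character(0)
  n <- design$display_size
  for (i in seq_len(nrow(d))) {
    line <- i + 1L  # header occupies line 1
    ds <- strsplit(d$displayed[i], "")[[1]]
    rs <- if (nzchar(d$reported[i])) strsplit(d$reported[i], "")[[1]] else character(0)
    if (length(ds) != n) {
      probs <- c(probs, sprintf("line %d: %d displayed symbols (expected %d)",
                                line, length(ds), n))
    } else if (anyDuplicated(ds)) {
      probs <- c(probs, sprintf("line %d: duplicate displayed letters", line))
    } else if (!all(ds %in% design$letter_set)) {
      probs <- c(probs, sprintf("line %d: displayed symbol outside letter set",
                                line))
    }
    if (length(rs) && !all(rs %in% LETTERS)) {
      probs <- c(probs, sprintf("line %d: reported symbols must be A-Z", line))
    }
  }
  if (length(probs)) {
    stop("invalid trial rows:\n  ", paste(probs, collapse = "\n  "))
  }
  d$score <- trial_scores(d)
  if (any(d$score > n)) stop("trial score exceeds display size")
  d
}

#' Write whole-report trials to CSV
#'
#' @param trials Trial data frame (as from \code{\link{simulate_session}}
#'   or \code{\link{read_trials}}).
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_trials <- function(trials, path) {
  cols <- c("subject_id", "session", "trial_index", "exposure_ms",
            "masked", "displayed", "reported", "is_practice")
  d <- trials[, cols]
  d$masked <- as.integer(d$masked)
  d$is_practice <- as.integer(d$is_practice)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' One fitted-parameter record
#'
#' Flattens a fit into the tabular interchange format: capacity
#' probabilities pi_1..pi_n, expected K, C, t0, mu, log-likelihood, clamp
#' flag, error rate and trial count.
#'
#' @param fit A \code{\link{fit_tva}} result.
#' @param subject_id,session Identifiers stamped on the record.
#' @return One-row data frame.
#' @export
parameters_record <- function(fit, subject_id = "s1", session = 1L) {
  stopifnot(inherits(fit, "tva_fit"))
  p <- fit$par
  rec <- data.frame(subject_id = subject_id, session = as.integer(session),
                    stringsAsFactors = FALSE)
  for (k in seq_along(p$k_dist)) rec[[paste0("pi_", k)]] <- p$k_dist[k]
  rec$expected_K <- p$expected_K
  rec$C <- p$C
  rec$t0 <- p$t0
  rec$mu <- p$mu
  rec$log_likelihood <- fit$logLik
  rec$t0_clamped <- as.integer(fit$t0_clamped)
  rec$error_rate <- fit$error_rate
  rec$n_trials_fit <- fit$n_trials_fit
  rec
}

#' Fit every subject-session in a trial table
#'
#' Splits the trials by subject and session, fits each block with
#' \code{\link{fit_tva}} and stacks the parameter records.
#'
#' @param trials Trial data frame covering one or more subject-sessions.
#' @param design A \code{\link{whole_report_design}}.
#' @param settings A \code{\link{fit_settings}}.
#' @return Data frame of \code{\link{parameters_record}} rows.
#' @export
fit_trials <- function(trials, design = whole_report_design(),
                       settings = fit_settings()) {
  key <- interaction(trials$subject_id, trials$session, drop = TRUE)
  recs <- lapply(split(trials, key), function(d) {
    fit <- fit_tva(d, design, settings)
    parameters_record(fit, d$subject_id[1], d$session[1])
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Write / read fitted-parameter tables
#'
#' Round-trippable flat CSV of \code{\link{parameters_record}} rows.
#'
#' @param params Parameter-record data frame.
#' @param path CSV path.
#' @return \code{path} (write) or the data frame (read).
#' @export
write_parameters <- function(params, path) {
  utils::write.csv(params, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Run manifest
#'
#' Provenance record written next to generated outputs: seed, package
#' version, timestamp and free-form configuration fields.
#'
#' @param seed Integer seed of the run.
#' @param ... Further named fields recorded verbatim.
#' @return Named list of class \code{"tva_manifest"}.
#' @export
run_manifest <- function(seed, ...) {
  structure(list(seed = seed,
                 package = "tvawr",
                 version = as.character(utils::packageVersion("tvawr")),
                 timestamp = format(Sys.time(), tz = "UTC",
                                    "%Y-%m-%dT%H:%M:%SZ"),
                 ...),
            class = "tva_manifest")
}
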