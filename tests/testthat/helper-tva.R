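# Shared fixtures: the standard seven-condition design, a reference
# parameter set, and quick fit settings for tests that exercise the
# optimiser without needing full multistart depth.

std_design <- whole_report_design()

ref_par <- tva_par(k_dist = c(0, 0, .2, .6, .2, 0), C = 22, t0 = 30, mu = 90)

quick_settings <- fit_settings(n_starts = 5, seed = 1)

# Random valid parameter draw for property-style loops.
random_par <- function(display_size = 6) {
  w <- stats::rgamma(display_size, 1)
  tva_par(w / sum(w), C = stats::runif(1, 8, 60),
          t0 = stats::runif(1, 0, 40), mu = stats::runif(1, 0, 150))
}

# Trial rows built directly from displayed/reported strings.
make_trials <- function(displayed, reported, exposure_ms = 80,
                        masked = TRUE, is_practice = FALSE) {
  k <- length(displayed)
  data.frame(subject_id = rep("s1", k), session = rep(1L, k),
             trial_index = seq_len(k),
             exposure_ms = rep_len(exposure_ms, k),
             masked = rep_len(masked, k),
             displayed = displayed, reported = reported,
             is_practice = rep_len(is_practice, k),
             stringsAsFactors = FALSE)
}
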