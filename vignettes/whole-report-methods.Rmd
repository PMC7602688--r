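---
title: "Whole-report modelling of visual attention: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-report modelling of visual attention: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tvawr)
```

## The observation model

A whole-report trial flashes `n` distinct letters (default 6, from a
20-letter alphabet) for a nominal exposure `T` ms. Encoding is an
exponential race with equal per-letter rate `v = C / n` per second:
whole report uses homogeneous targets, so equal attentional weights are
assumed and the total processing speed `C` (Hz) is split evenly.
The effective exposure is `max(0, T - t0)` for masked displays and
`max(0, T - t0 + mu)` for unmasked ones: `t0` (ms) is the perceptual
threshold below which nothing is encoded, and `mu` (ms) credits
unmasked displays with the extra encoding time afforded by iconic
persistence after stimulus offset. `mu` is constrained non-negative —
removing a mask cannot reduce the usable exposure — while `t0` may go
negative during unconstrained optimisation (see the clamp rule below).

Short-term memory capacity `K` is a random variable per trial with a
probability distribution over `1..n` (5 free parameters at `n = 6`);
the reported summary is its expectation. Given capacity `k` and
per-letter encoding probability `p = 1 - exp(-(C/n) tau / 1000)`, the
correct-report score follows a binomial distribution truncated at `k`,
with the tail mass collapsed onto `k` (the `k` fastest letters win the
race). The session likelihood multiplies these mixture probabilities
over the per-condition score counts.

Two modelling choices are worth making explicit:

* **The score is the sufficient statistic.** With equal weights the
  letter identities and positions carry no extra information about
  `(K, C, t0, mu)`, so the likelihood uses only the per-condition
  counts of trials scoring `0..n`. Intrusion errors are deliberately
  excluded from the likelihood and summarised separately as the error
  rate (intruded letters over reported letters); participants are
  instructed to avoid guessing, and an explicit guessing process would
  add parameters the 140-trial design cannot support.
* **Capacity support starts at 1, not 0.** A subject who can never
  store a letter is indistinguishable from one with an infinite
  threshold; keeping `K >= 1` matches the 5-degree-of-freedom
  accounting and avoids that confound.

The model is the minimal 8-parameter structure consistent with this
paradigm; it does not model exposure-duration jitter, mask-dependent
decay beyond `mu`, serial-position effects, or guessing corrections.

## Estimation

`fit_tva()` maximises the multinomial log-likelihood over transformed
parameters: the capacity distribution through a log-ratio (softmax)
transform with the last category as reference, `log C`, unconstrained
`t0`, and `log mu`. The likelihood is multimodal in small samples, so
the optimiser (Nelder–Mead followed by a BFGS polish, relative
tolerance `1e-10`, iteration cap 1000 per start) runs from 20 starting
points by default: the first is a deterministic heuristic — `t0` at
half the shortest exposure, `C` from the initial slope of mean score
against masked exposure (`E[score] ≈ C·tau/1000` for small `tau`),
uniform capacity distribution, `mu` at 60 ms — and the rest jitter it
under a seeded RNG, so fits are exactly reproducible given
`fit_settings(seed =)`. The best start by log-likelihood wins; exact
ties go to the lowest start index. Parameter excursions beyond
physically meaningless magnitudes (`C` or `mu` above 10^4, `|t0|` above
10^4 ms) and any parameter assigning zero probability to an observed
score return a large penalty instead of `-Inf`, keeping the optimiser
on finite ground.

**Threshold clamp.** If the best unconstrained solution has `t0 < 0`,
the data are refitted with `t0` frozen at 0 and the result flagged
`t0_clamped`; the reported fit is the clamped one, and the refit can
never exceed the unconstrained optimum's likelihood. On data generated
at `t0 = 0` roughly half the single-session fits clamp, which the
acceptance suite checks.

**Identifiability guards.** Fitting requires at least two distinct
exposure durations with trials (otherwise `C` and `t0` trade off
freely) and a non-empty score table; both violations are errors, as is
optimizer failure across all starts. Practice trials are always
excluded. Durations are milliseconds throughout, `C` is in Hz, and the
1/1000 conversion lives in one place (the encoding probability).

## The simulator and the generators

`simulate_trial()`/`simulate_scores()` draw from the generating race
process itself — capacity from its distribution, exponential finishing
times, truncation to the `k` fastest — so their empirical score
distribution is, by construction, the quantity the closed-form mixture
states. This makes the simulator an independent oracle for the model
code: the test suite and acceptance script compare empirical
frequencies from 10^5-trial runs against the closed form at random
parameter draws and require agreement within 4 Monte-Carlo standard
errors per cell. Intrusions are simulated as at most one guessed
out-of-display letter per trial with a fixed probability — the simplest
process producing realistic error rates (~0.09–0.11) without entering
the likelihood.

The cohort generators define the study conditions the pipeline is
validated under:

* `generate_cohort()` emulates a case-control design: 70 patients and
  140 controls (2:1), additive group shifts of −0.334 letters (expected
  K), −6.585 Hz (C) and +7.828 ms (t0), age slopes of −0.020
  letters/yr, −0.337 Hz/yr and +0.407 ms/yr, and a −6.684 ms male–female
  difference on t0 — magnitudes of the size reported for chronic-stroke
  cohorts on this paradigm. Control reference means (3.07 letters,
  27.84 Hz, 25.20 ms, error rate 0.11) anchor the scales. Between-
  subject SDs are set slightly below the observed total SDs because the
  age slopes contribute part of the spread. Observed outcomes add
  measurement noise (0.15 letters, 3 Hz, 6 ms, 0.02) emulating
  single-session estimation error; latent values are truncated to
  physical ranges (`C > 0`, `t0 >= 0`, expected K inside its support).
  Clinical labels (severity score, stroke-subtype class, lesion
  location) follow realistic frequencies but are *not* generatively
  linked to the attention parameters — they exist to exercise the
  pipeline, so their null associations double as a calibration check.
* `generate_longitudinal()` emulates six repeated sessions during a
  training programme in 54 patients: linear practice trends (0.090
  letters, 2.004 Hz, −2.502 ms, +0.006 per session), subject random
  intercepts sized to hit target intraclass correlations (0.80 for K,
  0.72 for C, 0.58 for t0, 0.65 for error rate) via
  `sd_w = sd_b * sqrt((1 - icc)/icc)`, subject-specific slope
  deviations, and a sham/active arm split with zero true arm effect.
  The target ICC refers to the latent stationary component; estimates
  from noisy or fitted data attenuate below it, and practice trends
  push the one-way estimator further down, so recovered ICCs are
  expected somewhat under target.
* `generate_cogmed()` emulates 10 training tasks over 17 sessions with
  a subject-level latent gain factor loading on every task's
  improvement slope. When coupled to a longitudinal panel, the latent
  gain is a weighted sum of the standardised attention-parameter slope
  deviations (positive on capacity and error rate, negative on
  threshold, zero on speed by default), reproducing the qualitative
  association pattern between training gain and parameter change.

What the generators deliberately do **not** reproduce: real lesion
anatomy, floor/ceiling and asymptotic learning curves (trends are
linear, matching the slope-based analyses), non-normal subject
distributions, and any generative link from clinical labels to
performance. Passing tests therefore demonstrate that the pipeline
recovers what these additive Gaussian processes plant and stays
calibrated under their null — not that real data meet those
assumptions.

## Statistical pipeline choices

* **Effect sizes.** Cohen's d is `2t / sqrt(df)` with the residual df
  of the fitted model (e.g. 206 at n = 210 with intercept, group, age,
  sex), preserving sign.
* **Families.** Bonferroni correction uses the number of outcome
  models (m = 4), flagging `p < alpha/m`; the flag is a pure function
  of p and m.
* **Categorical clinical predictors** are tested by the nested-model F
  (full vs covariate-only), giving df `(levels - 1, n - levels - 2)`;
  levels with fewer than two subjects are dropped with a warning, and
  a single remaining level is an error.
* **ICC flavour.** One-way random effects: sessions are exchangeable
  replicates, not fixed raters, which is the natural reading of
  repeated identical assessments. The imbalance-adjusted replicate
  count `k0 = (N - sum(n_i^2)/N)/(a - 1)` handles missing cells, and
  the 95% CI is Searle's F interval. Negative point estimates are
  preserved (truncation, if any, belongs to the reporting layer).
* **Two-sample t.** Welch (unequal variances) by default, from raw
  vectors or from (mean, sd, n) summaries; the summary route enables
  checks against printed tables.
* **Slopes and sessions.** Sessions are coded 1..S; per-subject slopes
  are plain OLS. The training-gain composite z-scores per-task slopes,
  takes the first principal component, and fixes its sign so the mean
  loading is positive — higher score = more improvement; the sign of a
  principal component is otherwise arbitrary.
* **Mixed models.** `outcome ~ session + age + sex + arm +
  session:arm` with a subject random intercept, fitted by REML
  (`lme4`). p values and CIs use a t distribution on `N - p` residual
  df. This is an approximation — exact small-sample df for mixed models
  are themselves model-dependent — but for within-subject contrasts at
  these panel sizes it is accurate, and the null-calibration suite
  verifies the interaction test holds its nominal 5% level.

## Validation scale and numerical notes

The test and acceptance suites run at sizes chosen to give stable
checks at desk scale: oracle comparisons use 25 random parameter draws
at 10^5 trials; parameter recovery pools 50 simulated sessions
(7000 trials) and contrasts mean absolute error at 140 vs 1400 trials
per fit over 6 replicates; the clamp check fits 10 zero-threshold
sessions; ICC recovery uses 500 subjects by 6 sessions at a true
variance ratio of 0.75; null calibration runs 500 replicate datasets
per stage at reduced cohort sizes (20/40 case-control, 24 subjects by
3 sessions for the mixed model); planted-effect checks use the full
default cohort (70/140) and panel (54 by 6). Score distributions sum
to 1 within 1e-12; the capacity simplex tolerance is 1e-9.

## Known limitations

* The likelihood ignores letter identity, position and report order;
  paradigms with inhomogeneous displays need attentional weights this
  model intentionally omits.
* `mu` is identified only through the two unmasked conditions; designs
  without unmasked exposures should fix it at 0.
* The residual-df p values for mixed models are approximate; random
  slopes are present in the generator but not in the fitted model,
  which is the usual analysis choice but mildly anticonservative when
  slope variance is large.
* Single-session fits at 140 trials carry substantial estimation noise
  (mean absolute error around 0.2 letters for expected K, ~10% for C);
  reliability and group analyses should treat that noise as part of
  the measurement model, as the generators do.
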