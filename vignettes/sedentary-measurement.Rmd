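---
title: "Measuring sedentary behaviour in youth: reduction, scoring and agreement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring sedentary behaviour in youth: reduction, scoring and agreement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sedvalid)
```

## The measurement problem

Sedentary time in children and adolescents can be measured two ways that
do not agree by construction. A waist-worn uniaxial accelerometer counts
every worn minute below an intensity cut-point as sedentary, whatever
the child was doing. A short questionnaire asks about a handful of named
sitting activities — watching television, using a computer, playing
console games, and either passive play (children, reported by a parent)
or studying (adolescents, self-reported) — and therefore measures a
deliberately narrower construct. Field studies that validate such
questionnaires report two things: *test-retest reliability* (agreement
between two administrations, Q1 and Q2, a couple of weeks apart) and
*concurrent validity* (agreement between Q1 and the accelerometer worn
in the same window). `sedvalid` implements both measurement arms and
the agreement-statistics suite those studies tabulate, and ships a
synthetic-cohort generator with known ground truth so the whole
pipeline can be validated end to end — which matters because the field
datasets behind such studies are rarely public.

## Accelerometer reduction

The reduction follows the standard youth waist-worn protocol, every
threshold applied with the strict inequality its wording implies:

1. **Minute aggregation.** Raw epochs (5 s by default; any length
   dividing 60 s) are summed into counts per minute (cpm); a trailing
   incomplete minute is dropped.
2. **Malfunction.** Minutes with *more than* 20,000 cpm are excluded
   (per minute, not per day — 20,000 itself is retained).
3. **Non-wear.** Maximal runs of consecutive zero-cpm minutes *longer
   than* 20 min are excluded as non-wear. A 20-min run is wear; any
   non-zero minute breaks a run. Runs are found on the continuous
   minute stream, so an overnight gap spanning midnight is one run.
4. **Sedentary time.** Worn minutes *below* 100 cpm (100 itself is not
   sedentary).
5. **Day validity.** The delivery and return days are removed; a day is
   valid when it holds at least 480 min (8 h) of wear. The 8-h rule can
   be switched off (`min_wear_min = 0`) for protocols that treat it as
   an instruction rather than a criterion.
6. **Standardisation.** Daily sedentary minutes are rescaled by the
   proportion of wearing time to a common reference:
   `sed / wear * reference`. The default reference is the participant's
   mean wear over valid days; a fixed reference (e.g. 960 min) can be
   supplied.
7. **Weekly summary.** At least 3 valid days including 2 weekdays and
   1 weekend day are required (otherwise an insufficient-data error
   naming the missing stratum). Weekday and weekend means combine as
   `(5·weekday + 2·weekend)/7`, and the total is classified against the
   guideline of less than 120 min/day of screen/sitting time (strict
   `<` by default; `inclusive = TRUE` gives the `≤` variant some
   tabulations use).

Day boundaries sit at local midnight; weekday/weekend comes from the
ISO calendar (Monday–Friday vs Saturday–Sunday).

## Questionnaire scoring

Eight items: four activities × weekday/weekend minutes per day. Segment
scores are plain sums; the weekly total uses the same 5/2 weighting as
the accelerometer so the two instruments share a scale. Missing items
are handled complete-case and segment-wise: a segment score exists only
when all four of its items are present, and the weekly total only when
both segments are complete. No imputation. Responses can arrive as open
minutes (the default) or as categorical duration bands mapped to
configured midpoints (`map_duration_bands()`).

## Agreement statistics

All statistics are implemented from first principles in this package;
base R's `cor`, `cor.test`, `chisq.test` and `e1071::classAgreement`
appear only as independent cross-checks in the test suite.

- **Spearman rho** — Pearson correlation of mid-ranks (ties get average
  ranks); two-sided p from the t-approximation with n−2 df, or exact
  permutation by full enumeration for n ≤ 8. rho ≥ 0.30 is flagged as
  the conventional "acceptable" threshold.
- **Quartile bins** — rank-block binning, `ceiling(4·rank/n)`, each
  method binned on its own distribution. This keeps the marginals as
  uniform as ties allow, which is the point of a quartile agreement
  analysis; a sample-quantile cut is available for sensitivity checks.
- **Cohen's kappa** — `(p_o − p_e)/(1 − p_e)`; used on the binary
  guideline classification. k ≥ 0.40 flagged as acceptable.
- **Quadratic-weighted kappa** — disagreement weights
  `((i−j)/(K−1))²`; reduces exactly to the unweighted kappa at K = 2
  (property-tested exhaustively).
- **Bland–Altman** — bias = mean(questionnaire − reference), sample SD
  (n−1), limits of agreement `bias ± 1.96·SD` with 1.96 verbatim, not a
  t-quantile. The orientation makes systematic under-reporting a
  negative bias; a reversed orientation flips every sign exactly.
- **Pitman trend** — two variants, because the literature is ambiguous
  about which is "the" Pitman test in this setting: *classic*
  correlates the signed difference with the pair mean (the proper
  Pitman equal-variance test under bivariate normality), *absolute*
  (default in validity reports) correlates |difference| with the mean,
  the form usually footnoted next to Bland–Altman tables.
  Heteroscedasticity is declared when r > 0 and two-sided p < 0.05.
- **Chi-square goodness of fit** — `Σ(O−E)²/E`, df = categories − 1;
  for comparing subsample composition against the full sample.

p-values use t-approximations rather than exact permutation by default:
validation studies report significance stars at n in the dozens to
hundreds, where the approximation is more than adequate. The exact
option is capped at n ≤ 8 where full enumeration (8! orderings) is
cheap; beyond that the approximation is the better tool anyway.

## The synthetic cohort generator

`sim_config()` fixes the study conditions; `simulate_study()` emits a
linked cohort: ground truth, Q1, Q2 and an accelerometer arm.

**Truth.** Per-day true sedentary minutes are drawn normal by day type
and clamped to `[0, scheduled wear]`. Defaults anchor to the
objectively measured levels reported for South American school-age
cohorts: children 522 (weekday) / 547 (weekend) min/day, adolescents
570 / 599, with per-day SDs of 60 / 80 min — the means are published
medians used as plausible anchors; the SDs are our choice of realistic
day-to-day variability, set once. Wear is scheduled 08:00–20:00
(720 min/day) for 7 days starting on a Monday.

**Counts.** Each day's stream covers the full 24 h at 5-s epochs.
Within the wear window the rounded true number of sedentary minutes is
placed at random positions with cpm uniform on [1, 99] and the rest
uniform on [100, 6000]; outside the window everything is zero. Only the
100-cpm boundary matters to the reduction, so the within-class shape is
deliberately flat; sedentary minutes start at 1 cpm rather than 0 so
that a zero count is an unambiguous non-wear marker and the no-gap
round trip is exact to ±1 min/day (the rounding of the truth).
Injected non-wear gaps are Poisson per day (default rate 1/day) with
exponential lengths (mean 45 min) truncated below at 21 min so every
injected gap is detectable by the 20-min rule; gaps are placed without
overlap inside the wear window.

**Questionnaire.** The four items cover a configurable share
`1 − underreport_fraction` of true sedentary time (default fraction
0.75: published questionnaire medians sit near a quarter of the
accelerometer medians), split across items by a per-participant
symmetric Dirichlet (concentration 1) so item sums stay exact. Reported
segment totals add Gaussian noise (SD 30 min by default) and clamp at
zero.

**Retest coupling.** Q1 and Q2 share a per-segment Gaussian latent:
`W_a = λU + √(1−λ²)V_a`. Writing the target Spearman correlation of
weekly totals as a Pearson correlation through the bivariate-normal
relation `r = 2·sin(πρ/6)`, the required noise correlation `c` solves
`r = (var(R) + c·var(E)) / (var(R) + var(E))`, where `var(R)` is the
truth-derived variance of reported totals (known from the config) and
`var(E)` the reporting-noise variance; then `λ = √|c|` with a sign flip
on `U` for negative `c`. The clamp at zero is ignored in this
calibration — at the default operating point the reported totals sit
more than five noise SDs above zero, and Monte-Carlo tests confirm the
realised rho is unbiased across the 0.3–0.7 grid (±0.023 SE at
n = 1000). Targets the geometry cannot reach (e.g. ρ < 1 with zero
noise, or below the correlation floor set by the truth variance) raise
a configuration error rather than silently missing.

**Accelerometer arm.** `simulate_study(accel = "stream")` synthesises
the epoch streams and runs them through the full reduction. The study
pipeline standardises to the *scheduled* wear window (720 min) rather
than the participant's observed mean wear: with injected gaps the
observed-wear reference would rescale sedentary time downward and bias
the validity arm by construction, which is a property of the reference
choice, not of the questionnaire. (`reduce_accel()` itself keeps
participant-mean wear as its default, the usual choice for real data
where the scheduled window is unknown.) `accel = "summary"` skips the
streams and emits idealised truth-level summaries — useful for large
reliability-only cohorts.

**What the generator does not emulate.** No biomechanical realism in
the count stream (no intensity autocorrelation, no posture), no
triaxial vector magnitude, no seasonal or day-of-week behavioural
structure beyond the weekday/weekend split, no participant-level
heterogeneity beyond day-to-day variation, and reporting noise that is
mean-zero by construction — real self-report error is likely skewed.
Passing round-trip and recovery tests therefore show the *pipeline* is
correct and calibrated, not that any particular field questionnaire is
valid.

## Worked example

```{r example}
cfg <- sim_config(n_participants = 60, group = "children", seed = 42)
study <- simulate_study(cfg, accel = "summary")
rel <- run_reliability_study(study, "children")
format_reliability_report(rel)
val <- run_validity_study(study, "children")
format_validity_report(val)
```

With the default conditions the reliability table shows a total-days
rho near the configured 0.70, and the validity table a strongly
negative bias near `-0.75 × 529 ≈ -397` min/day with wide limits of
agreement — the signature of a questionnaire that captures only part of
total sedentary time.

## Study accounting and planning

`study_accounting()` reproduces multi-stage response-rate arithmetic
(first administration over eligible; retest and accelerometer over
first-administration completers; percentages rounded half-up to one
decimal), and `plan_sample()` the loss-inflation arithmetic
`floor(n·(1+loss))` used to pad power-derived sample sizes (136 → 170,
65 → 81 at 25%).

## Numerical choices and problem sizes

Medians and percentiles use the linear-interpolation convention
(`quantile` type 7); report cells round minutes to one decimal and
coefficients to two, with full precision kept in the machine-readable
tibbles. The test suite and the acceptance script run cohorts of
n = 1000 for correlation recovery (questionnaire arms only) and
n = 400 with full epoch-stream reduction for bias recovery — sizes
chosen so Monte-Carlo error is a fraction of the tolerances being
checked; the Pitman type-I simulation uses 2000 replicates of n = 50.
Reproducibility is strict: every generator output is a pure function of
(config, seed), with per-participant sub-seeds drawn once inside
`simulate_cohort()`.

## Known limitations

- The exact wear-time standardisation formula used by any given field
  study is rarely printed; the proportional form implemented here is
  the natural reading, with the reference period configurable.
- Kappa and LOA confidence intervals, ICCs and regression-based LOA are
  out of scope.
- The guideline threshold, like every cut-point, is configurable but
  the defaults are the strict readings; sensitivity to the `≤` variant
  is left to the user.
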