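---
title: "Behavioral early-warning scores: model, simulator and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behavioral early-warning scores: model, simulator and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The idea being benchmarked

Nurses and other clinicians interact with the clinical information system
(CIS) far more often when they are worried about a patient: vitals get
re-measured at unscheduled hours, flowsheet comments appear, PRN medications
are given, scheduled medications are withheld, notes are written. Those
actions are timestamped as a side effect of routine charting, so the
*frequency* of documentation — not the charted values — carries a signal of
clinical concern that can precede physiological deterioration by a day or
more. `concernews` packages a desk-scale, fully synthetic benchmark of that
idea: a cohort generator with an explicit latent concern process, an hourly
behavioral feature extractor, a green/yellow/red reference scorer, MEWS/NEWS
physiology comparators, and two evaluation instruments — a
time-varying-covariate Cox model and a lead-time likelihood ratio.

Everything here runs on simulated data. The point of the package is not to
reproduce any hospital's numbers but to provide a tested, reproducible
implementation of the full analysis pathway in which each claimed property
(early separation, null calibration, parameter recovery) is checkable
against a generative truth.

## The synthetic cohort generator

Each encounter draws an age (normal, mean 65, sd 15, clamped to 16–100), a
care unit (60% med-surg, 25% stepdown, 15% ICU), an admission instant in
2015–2018, and a length of stay (log-normal, median 96 h, clamped to
8 h–60 d). A fraction `event_fraction` of encounters experiences the
composite outcome — first occurrence of mortality, cardiac arrest,
unanticipated ICU transfer, rapid response, or sepsis. Events are assigned
by a *constant hazard*: one exponential rate, solved so that the expected
share of encounters whose event precedes discharge equals `event_fraction`.
Constant hazard is deliberate. Any placement scheme that fixes the event
fraction per encounter (uniform or late-skewed positions within the stay)
makes elapsed time-at-risk genuinely prognostic of an imminent event once
lengths of stay are heterogeneous; since patient hour is a mandatory model
feature, a "null" cohort would then carry real temporal signal and
calibration checks would not probe the documentation features. Under
constant hazard, time-at-risk is uninformative by construction (up to a
small end-of-stay truncation effect), so the null really is null.

Two latent ramps drive an event encounter (non-event encounters have both
identically zero):

* concern `c(t)`: 0 until `behavioral_onset_hours` (default 48) before the
  event, then linearly rising to 1 at the event;
* physiological drift `d(t)`: the same shape over
  `physiological_onset_hours` (default 6), scaled by `drift_max`.

Thirteen documentation streams (five vital measurements, five vital
comments, PRN administrations, withheld scheduled medications, notes) are
inhomogeneous Poisson processes with hourly rate

```
base_rate * schedule_weight(hour of day) * (1 + multiplier * c(t))
```

plus *forced* routine vitals — all five kinds charted together — at every
schedule hour (default every 4 hours). Note events carry tags from a fixed
21-concept vocabulary; the tag intensity rises with concern through the same
multiplier as the note rate, so zeroing the multipliers removes the
behavioral signal entirely. Vital values are drawn around a mean that
interpolates from a normal-range center toward a MEWS/NEWS-abnormal target
as `d(t)` rises, with draws clipped to ±2 sd, so a calm patient scores
exactly 0 on both comparators. Consciousness is "A" unless `d > 0.8`, and
SpO2 rows carry a supplemental-oxygen flag once `d > 0.5`.

### Why these defaults

The defaults define the benchmark's study conditions and are chosen once:

* `event_fraction = 0.3`. Deliberately enriched relative to ward
  prevalence, as is usual for method-evaluation simulations: with cohorts of
  a few hundred encounters it keeps scores of events in every risk band, so
  hazard ratios, their confidence intervals and the per-level likelihood
  ratios are estimable without pooling heroic numbers of replicates.
* Base rates (0.06/h per vital measurement beyond the schedule, 0.02/h per
  comment stream, 0.04/h PRN, 0.01/h withheld, 0.10/h notes) give roughly
  40 discretionary documentation events per patient-day on top of the 30
  forced vital entries — busy-ward orders of magnitude, stated as
  assumptions, not measurements.
* `concern_multipliers = 3` (a 4× rate at full concern) plants an effect
  large enough that a 48-hour behavioral onset is detectable from a few
  hundred encounters, the sample size the package's examples and tests use.
* The day shift (07:00–20:00) charts at weight 1.3 vs 0.7 overnight, which
  makes "common documentation hours" learnable and non-trivial.

What the generator does **not** emulate: real physiology (each vital is an
independent noisy channel), back-charting and timestamp distortion,
multi-unit transfers, inter-site EHR dialects, free-text notes (concept tags
are attached directly), and encounter-level heterogeneity in documentation
style. Passing tests therefore demonstrate the *pipeline's* correctness and
calibration under the stated generative structure — not performance on real
EHR data, where confounding between staffing, acuity and documentation is
far richer.

## Inclusion filters

`apply_inclusion_filters()` retains adult (≥ 18 y), non-hospice encounters
with unit stays of more than 24 hours and at most 60 days. Boundaries are
literal: exactly 24 h is excluded, exactly 60 d retained, age 18.0 retained.
The per-rule exclusion tally (an encounter violating several rules counts
under each) is attached to the result, mirroring cohort-attrition reporting.

## The hourly feature matrix

One row per inpatient hour per encounter, 55 feature columns:

* 30 measurement columns — the 15 base features (5 measurement counts, the
  all-five-vitals-together and single-vital episode counts, 5 comment
  counts, PRN, withheld, notes) each split into counts at *common* vs
  *uncommon* documentation hours;
* 21 note-concept counts;
* 4 temporal features: month (1–12), day of week (Monday = 0), hour of day
  (0–23), patient hour (hours since admission).

All counts are trailing 12-hour sums, closed on the right at the end of the
row's hour, so every cell is computable in simulated real time. The window
is adaptive at the start of the stay (shorter than 12 h until hour 11).

Conventions the field leaves open, fixed here and tested:

* "Same time" for the all-five-vitals feature means the same 5-minute
  timestamp bin (one charting action).
* A vitals-taking *episode* is a maximal run of vital measurements with
  gaps under 15 minutes; the single-vital feature counts episodes of
  exactly one measurement. Both episode features are counts of qualifying
  occurrences, so the partition identity common + uncommon = total holds
  for all 15 base features.
* Common hours are learned per feature, pooled across units: an hour of day
  is common when its empirical share of events is at least 1/24 (at or
  above uniform density). Features with under 100 training events fall back
  to the configured vitals schedule, with a warning.

## Scoring

**Reference behavioral scorer.** A pooled (discrete-time) logistic
regression of "first composite event within the next H hours" (H = 12) on
the 55 features, one observation per patient-hour, split into train/test by
encounter — never by row. The continuous score is the predicted probability;
categorical green/yellow/red comes from the 0.80/0.95 quantiles of the
training-score distribution, so about 15% of training hours are yellow and
5% red. A weak L2 penalty (lambda = 1, standardized predictors, intercept
unpenalized, damped-Newton IRLS) is the default fit: with 55 count columns
and desk-scale cohorts, rare columns otherwise produce quasi-separation.
`regularize = "none"` gives the plain ML fit and fails loudly on
separation. `crossfit_concern_scores()` scores every encounter with a model
trained on the other fold(s), which the pipeline uses so that evaluation
never sees in-sample scores.

**Prospective stamping.** The score computed from the window ending at hour
t is stamped at patient hour t + 1 and governs the Cox interval
(t + 1, t + 2]. This one-hour lag makes every score a function of strictly
earlier data. It matters: the event stream stops at the event, so the
window of the event's own hour "sees" documentation stop mid-hour — without
the lag that truncation leaks outcome information into the covariate at
exactly the event interval and biases null hazard ratios below 1.

**Comparators.** MEWS (systolic BP, heart rate, respiratory rate,
temperature, AVPU; bands low 0–2 / moderate 3–4 / high 5+) and NEWS
(respiratory rate, SpO2, supplemental O2, temperature, systolic BP, heart
rate, consciousness; low 0–3 / moderate 4–6 / high 7+) are computed from
the standard published component tables bundled as versioned CSVs under
`inst/extdata/` with provenance headers. Vitals are last-observation-
carried-forward with a 12-hour staleness limit; an hour missing any
component is scored missing and excluded from models rather than imputed.

## Evaluation

**Time-varying Cox model.** Hourly categories become counting-process
records — one (start, stop] interval per maximal run of a constant covariate
vector, at-risk time ending at the first event or discharge — and
`survival::coxph` fits the composite endpoint with Efron tie handling, the
low band as reference, and 95% Wald intervals on the log scale. Both the
single-system model (CONCERN moderate/high) and the combined six-indicator
model (CONCERN + MEWS + NEWS) are supported. The fit is validated against a
hand-derived three-subject partial-likelihood root and against planted
hazard-rate multipliers recovered within a few percent at 2,000 encounters.

**Lead-time likelihood ratio.** For score level x and horizon h,

```
L(x, h) = P(x | event h hours in the future) /
          P(x | no event h hours in the future)
```

The numerator stratum holds patient-hours whose encounter's first event
falls exactly in hour bin t + h (a cumulative "within h hours" convention is
available via `convention = "cumulative"`); the denominator stratum holds
hours verified event-free through t + h. Hours censored within h hours are
excluded — their status at t + h is unknown. Both conditional category
tables are shrunk additively before the ratio: each frequency becomes
(p + k/s) / (1 + 3k/s) with k = 0.5 and s the smaller stratum size. For
balanced strata this is exactly classical add-k smoothing; using a common
pseudo-frequency keeps L finite, makes event/non-event relabeling invert L
exactly, and returns L = 1 for a level observed in neither stratum —
without that last property, a physiology score that is simply never "high"
far from events would show a spuriously enormous ratio at long horizons.
The estimator is noisy at large h, where few patient-hours sit exactly h
hours before an event; warning horizons from `lead_time_horizon()` (the
largest h with log L above log 1.5) should be read with that in mind.

## Problem sizes and numerical choices

The package's tests and examples use cohorts of 150–800 encounters, 50
replicates of 500 encounters for null calibration, 20 replicates at
n = 200 and n = 2,000 for parameter recovery, and 10 seeds for the
lead-time ordering — sizes at which every property is decidable in minutes
on a laptop while leaving visible sampling noise, which the tolerance bands
acknowledge. Other numerical choices: hour bins are left-closed [t, t+1);
within-bin ordering is draw order; ramp values are taken at hour midpoints
(so the linear ramp's hourly sum equals onset/2 exactly); vital draws are
clipped at ±2 sd and rounded to charting precision; timestamps are whole
seconds so CSV round trips are exact; all randomness flows through
`set.seed` with per-stage substreams derived from one global seed.

## Known limitations

* Effect magnitudes are set by the construction. The concern and drift
  ramps are deterministic, so at the default multipliers nearly every
  event encounter is red in its final hours and almost no event occurs
  from a green state; fitted hazard ratios can reach the hundreds or
  thousands with correspondingly wide intervals. The benchmark's
  informative outputs are structural — band ordering, warning-horizon
  gaps, null calibration, parameter recovery — not the absolute hazard
  ratios.
* The reference scorer is a transparent stand-in, not a production score:
  its coefficients are refit per cohort and its categorical cutpoints are
  quantiles, not clinically calibrated thresholds.
* The simulator's null is exactly exchangeable; real "null" wards are not,
  so null-calibration results bound optimism only under the stated model.
* MEWS/NEWS variants differ across hospitals (urine output, NEWS2 oxygen
  scales); the bundled tables are one published version each, and the
  choice is a config-level substitution point.
* With exact-horizon reading, L(x, h) uses one patient-hour per event per
  horizon; long-horizon curves need either pooling or the cumulative
  convention for tight estimates.
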