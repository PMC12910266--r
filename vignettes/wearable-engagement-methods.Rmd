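---
title: "Methods: engagement, retention and scan-proximity physiology in wearable cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: engagement, retention and scan-proximity physiology in wearable cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`scanwear` analyzes longitudinal digital-health data from surveillance
cohorts — here modeled on a hereditary-cancer (Li-Fraumeni syndrome, LFS)
clinic population of children and adults who wear a research-grade
smartwatch and answer daily stress surveys plus periodic psychosocial
questionnaires while undergoing scheduled imaging. The package has five
analysis stages (engagement metrics, retention survival analysis, spectral
periodicity, questionnaire scoring with a self-harm alert audit, and
per-scan-event additive modeling of minute-level physiology) and a synthetic
cohort generator that plants known ground truth for every stage. Because
clinical cohorts of this kind cannot be redistributed, the generator is a
first-class, tested component: every estimator in the package is validated
by recovering what the generator planted.

# Engagement metrics

A smartwatch day is *active* when valid wear minutes (already cleaned of
improper-wear artifacts upstream; the package takes per-day valid minutes as
input) reach a threshold, 6 hours by default, read inclusively
(`>= 360` minutes). A 1-hour variant supports the secondary wear definition.
A survey day is active when the daily stress measure was completed. The
engagement rate is active days over observed days; by default the observed
span runs from enrollment to the participant's last record (capped at the
180-day horizon), with a full-horizon denominator available as an option —
the denominator convention is genuinely ambiguous in practice, so both are
exposed and the choice is recorded in outputs.

Series are smoothed with a **centered 7-day rolling mean**. Edge windows are
truncated rather than dropped, which preserves series length for the
spectral stage; days with no record are excluded from the window mean
(treating them as zeros would bias the periodogram toward the missingness
pattern) but count as nonactive in rates. Watch-survey coupling is the
Pearson correlation of the two smoothed series on their day-aligned overlap;
a constant series returns `NA` with a warning, never a fabricated 0.

Group comparisons use the **Welch two-sample t test** (Satterthwaite
degrees of freedom, two-sided p), which tolerates unequal variances and the
heavily unbalanced child/adult split. No multiplicity correction is applied;
tables report raw p-values.

# Retention survival analysis

Disengagement is defined through a three-state day classifier. Every day is
first *active* or nonactive; nonactive days are provisionally *exit* and are
reclassified *inactive* when any later day is active. Exit labels therefore
survive only as one terminal contiguous run, and the **first sustained
exit** — the survival event — is the first day of that run. The event
counts within the 180-day horizon; participants whose exit begins later, or
who are active at the end of observation, are censored at
`min(observed days, 180)`. Two conventions deserve note:

* Days with no record at all are nonactive. A participant who stops syncing
  is a disengagement event, not a censoring — the quantity of interest is
  disengagement from the study, not device data availability.
* The event day is the *first* day of the terminal run (a "sustained exit"
  begins when activity stops). A participant never active has an event at
  day 0; the product-limit estimator handles zero-time events by the usual
  convention S(0-) = 1.

Kaplan-Meier curves, medians and IQR bounds (smallest time with survival at
or below 0.5, 0.75 and 0.25 respectively) come from the product-limit
estimator; 95% CIs for quantiles invert the log-log confidence band (the
Brookmeyer-Crowley construction — a conventional default where no method is
otherwise dictated). Strata are compared with the standard log-rank test.
The `survival` package provides the estimator and test; the package's own
contribution here, the day-state machine and event derivation, is validated
exhaustively against a brute-force implementation of the two-pass rule over
all boolean sequences up to length 10, and the survival internals are
checked against hand-computed product-limit and hypergeometric fixtures.

# Spectral periodicity

Each participant's smoothed engagement series is mean-subtracted (over
non-missing days), missing days are zero-filled *after* detrending
(unbiased under missingness unrelated to the signal), and a real-input FFT
yields magnitudes at positive frequencies; bin `k` of an `N`-day series
corresponds to a period of `N/k` days. The top three magnitudes define the
dominant periods, with magnitude ties broken toward the longer period.
Because periods live on the `N/k` grid, recovery tests assert the nearest
on-grid bin, never exact off-grid periods. Series shorter than 28 days (two
cycles of the shortest reportable biweekly period) are excluded from cohort
histograms. Note the 7-day smoothing acts as a low-pass filter: a 14-day
cycle survives with attenuated amplitude, while periods near one week are
strongly suppressed — cohort histograms should be read with this in mind.

# Questionnaire scoring and the self-harm alert

Four instruments are scored: PHQ-9 (9 items, 0-3), GAD-7 (7 items, 0-3),
PSS-4 (4 items, 0-4, items 2 and 3 reverse-scored), and the PROMIS
sleep-related-impairment short form (8 items, 1-5, reported as the raw sum —
group means near 16-23 are consistent with raw short-form sums, and no
T-score lookup is shipped). Incomplete responses are excluded and logged,
never prorated. Any positive PHQ-9 item 9 (self-harm) raises an alert;
alerting is an audited, non-blocking side channel, and the alert table is
checked to contain exactly one row per positive response. The daily stress
measure is a 0-3 ordinal whose top level is "very stressed"; the
stress-frequency metric is the fraction of *completed* surveys at that top
level (participants with no completed surveys are `NA`, excluded from group
tests). Group tests aggregate to one value per participant (the mean of
that participant's totals) before the Welch test, so n equals participants,
never responses — repeated measures must not masquerade as independent
replicates.

# Scan-proximity physiology (GAM stage)

For each eligible surveillance scan, minute-level physiology in the
half-open 3-day pre-scan window `[scan − 3 d, scan)` is modeled with an
additive model whose response is minutes-to-scan and whose features are the
five z-scored channels (log EDA, heart rate, log HRV, respiratory rate,
skin temperature) plus a missingness fraction. Choices worth recording:

* **Eligibility**: at least 2 scans, each preceded by at least 300 h of
  cumulative wear. 300 h cannot fit in the 72 h modeling window, so the
  wear requirement is evaluated over a separate 30-day look-back (a
  deliberate, configurable reading: eligibility measures sustained wear,
  not window coverage).
* **Scan timestamp**: midnight of the scan day unless a minute is supplied —
  clock times of scans are not part of the data model.
* **Imputation**: single deterministic chained-equation imputation — mean
  initialization, then 10 sweeps in which each channel is linearly regressed
  on the other four and its missing entries replaced by predictions.
  Observed values are never altered; the per-minute missingness fraction
  (missing channels / 5, values in {0, 0.2, ..., 1}) is recorded *before*
  imputation and enters the model as a feature, so a
  missing-not-at-random mechanism concentrated near scans is itself
  estimable. Channels under 20% observed flag the event (withheld, not
  imputed); a fully missing channel excludes it.
* **Transforms**: natural log on EDA and HRV (right-skewed, strictly
  positive), then per-event z-scoring; a constant channel is dropped with a
  warning rather than producing an undefined z-score.
* **Model**: one cubic regression spline per feature, no interactions,
  smoothing selected by REML. "Default hyperparameters" are pinned in this
  package's configuration — up to 20 basis functions per smooth, reduced
  automatically for low-cardinality features (the missingness fraction has
  at most six distinct values; below four distinct values a linear term is
  used). `mgcv` provides the spline/REML machinery.
* **Outputs**: 100-point partial-dependence grids per feature spanning the
  observed range; 5-fold row-wise cross-validated MSE (shuffled, seeded);
  and within-person conservation of physiological response quantified as
  the Pearson correlation of partial-dependence curves across a
  participant's scans, interpolated onto the intersection grid.

Within-day circadian structure is deliberately not removed from features or
response; with midnight-anchored scans, time-of-day is aliased into
time-to-scan, which is a recognized limitation of the design rather than a
bug — the within-person similarity comparisons are unaffected because the
aliasing is shared across a participant's events.

# The synthetic cohort generator

The generator emulates the study conditions: 9 children and 36 adults by
default, a 180-day follow-up target, biweekly check-in calls, and
enrollment rolling over six months. Its planted structure, all exposed in
`cohort_config()`:

* **Wear adherence**: the probability that day `t` is active is
  `base × 2^(−t/halflife) × (1 + m·sin(2πt/period))`, clamped to [0, 1] —
  baseline 0.81 (adults) / 0.56 (children) matching the reported percent
  days worn; decline half-life 540 days (a mild, realistic drift chosen
  once — engagement visibly declines over six months without collapsing);
  check-in period 14 days with relative amplitude 0.25 (the check-in cycle
  is visible but does not dominate). Each participant draws an individual
  baseline (SD 0.19 adults / 0.26 children, the reported between-person
  spreads), so per-participant rates are properly overdispersed.
* **Dropout**: geometric with per-day hazards `1 − 2^(−1/153)` (adults) and
  `1 − 2^(−1/77)` (children), so the planted median retention equals the
  153/77-day medians the retention stage must recover. Dropout is absorbing
  and truncates the record stream; because the analysis treats record-less
  days as nonactive, emitting explicit zero-wear rows instead would yield
  identical analyses, and truncation reproduces observed-span denominators.
  An optional re-entry probability generates post-gap activity to
  stress-test the day-state machine, which must handle re-entry even though
  the default generator never produces it.
* **Surveys**: completion probability is the survey adherence curve
  (baselines 0.65/0.51, same decay and sinusoid) shifted by
  `coupling × (watch_active − p_watch)` on the same day, planting the
  configured watch-survey coupling (default 0.7); completed days draw a 0-3
  stress level with top-level ("very stressed") probability 0.363 for
  children and 0.143 for adults.
* **Wear hours** on active days: per-participant mean around 17.6 h
  (adults) / 15.7 h (children), between-person SD 2.5 h, day-to-day SD
  1.5 h; about a quarter of wear falls in the nominal 23:00-07:00 sleep
  window. Sleep labels are generated directly, not inferred — sleep
  detection is treated as an upstream input.
* **Scans**: 17/45 of participants undergo imaging every ~90 days with a
  few days of jitter. Within the 3-day pre-scan window each channel adds a
  planted drift `amplitude × g(u)` (`u` = scan proximity in [0, 1];
  `g` flat, linear, quadratic or sigmoidal; log scale for EDA/HRV) to an
  individual baseline plus Gaussian noise; overlapping windows sum their
  effects. Every value is independently missing at the configured rate,
  optionally inflated toward the scan to plant a
  missing-not-at-random mechanism.
* **Instruments**: totals drawn per group around the reported means/SDs
  (PHQ-9 10.0/5.2 children vs 4.2/4.4 adults; PROMIS SRI 22.7 vs 16.5) and
  decomposed into in-range items. GAD-7 and PSS-4 group means are set
  nearly equal (6 vs 5, and 7 vs 6) — no group difference is planted where
  none was established. All instruments are administered every 14 days from
  day 0 while on study; the true battery schedule is heterogeneous, but a
  uniform biweekly cadence is the simplest schedule consistent with
  biweekly check-ins. With probability 0.11 a participant is an "alerter"
  with exactly one positive PHQ-9 item 9.
* **Composition**: all generated children are TP53 carriers by default
  (child noncarriers were not recruitable in the motivating study), but
  `prop_tp53_mut_children` can be lowered to generate them for confounding
  diagnostics.

What the generator does **not** emulate: real circadian physiology (worn
minutes are placed as simple within-day blocks), raw 64 Hz sensor
processing, family clustering of participants, informative dropout tied to
psychosocial state, and re-entry under the default settings. Passing
recovery tests therefore demonstrates estimator correctness under the
planted mechanisms, not robustness to every real-world pathology.

# Numerical and testing choices

Problem sizes were chosen so each validation isolates one mechanism at
adequate power: exhaustive day-state enumeration to length 10; survival
recovery at 200 participants per group over 100 replicates; periodogram
fixtures at 168 and 180 days (on-grid and off-grid planted periods);
GAM shape recovery at 4,320 rows (one fully-worn 3-day window) with noise
at half the signal SD; imputation comparisons over 100 seeds at 20%
deletion on channels correlated at 0.9. Degenerate inputs fail loudly and
specifically: empty series, empty pre-scan windows, non-positive EDA/HRV
before the log, constant channels, rank-deficient designs, strata with no
members. Determinism is part of the contract — a fixed configuration seed
makes every generated table byte-identical, and the pipeline manifest
records the seed with every run.

# Known limitations

* The alert prevalence and child retention median are extremely noisy at
  the default cohort size (9 children); that noise is the study condition,
  not an artifact.
* The chained-equation imputation is a single predictive-mean completion;
  it understates imputation uncertainty by design (the downstream model is
  fit once per event, not pooled over multiple imputations).
* Log-rank and Welch p-values are reported unadjusted across strata and
  instruments.
* The eligibility look-back (30 days) and the daily stress scale's exact
  item wording are package conventions where the upstream definitions are
  unspecified; both are configurable and recorded in outputs.
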