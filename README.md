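# scanwear

Analysis pipeline for longitudinal digital-health studies in
hereditary-cancer surveillance cohorts — the setting is a Li-Fraumeni
syndrome (LFS) clinic where children and adults wear a medical-grade
smartwatch, answer daily stress surveys and periodic psychosocial
questionnaires, and undergo scheduled imaging that brings anticipatory
stress ("scanxiety"). The package is for biostatisticians and digital-health
researchers who need to quantify *whether participants keep using the
tools*, *how their psychosocial state evolves*, and *whether wearable
physiology carries a signature of scan proximity* — and to validate all of
that against synthetic data with planted ground truth, since cohorts of
this kind cannot be redistributed.

## What it computes

**Engagement.** A watch day is active when valid wear minutes reach a
threshold (default ≥ 6 h); a survey day is active when the daily stress
measure was completed. Rates are active/observed days; series are smoothed
with a centered 7-day rolling mean, and watch–survey coupling is the
Pearson r of the two smoothed series. Groups (age, *TP53* status, cancer
history) are compared with the Welch test,
t = (x̄₁ − x̄₂)/√(s₁²/n₁ + s₂²/n₂) with Satterthwaite df.

**Retention.** Each day is classified active / inactive / exit by a
two-pass rule: nonactive days are provisionally *exit*, reclassified
*inactive* if any later day is active, so exit survives only as one
terminal run. The survival event is the *first sustained exit* — the first
day of that run — within a 180-day horizon; later exits and always-active
participants are censored. Kaplan–Meier curves Ŝ(t) = ∏_{tᵢ≤t}(1 − dᵢ/nᵢ)
with median/IQR and Brookmeyer–Crowley 95% CIs, and log-rank tests across
strata.

**Periodicity.** Per participant, the smoothed series is mean-subtracted
and Fourier-transformed; bin k of an N-day series is a period of N/k days,
and the 3 largest magnitudes are the dominant periods (biweekly check-in
cycles show up here).

**Psychosocial scores.** PHQ-9, GAD-7, PSS-4 (items 2–3 reverse-scored)
and PROMIS sleep-related impairment (raw sum), a "very stressed" frequency
from the daily measure, rolling-score matrices, per-participant aggregation
before Welch group tests, and an audited PHQ-9 item-9 self-harm alert
channel.

**Scan-proximity physiology.** For participants with ≥ 2 scans and ≥ 300 h
wear in a 30-day look-back before each scan, minute-level physiology in the
3-day pre-scan window is modeled per event as
time-to-scan ~ Σⱼ fⱼ(xⱼ), one cubic-spline smooth per z-scored channel
(log EDA, heart rate, log HRV, respiratory rate, temperature) plus a
missingness-fraction feature, REML smoothing, no interactions — after
chained-equation imputation of missing values. Outputs are
partial-dependence grids, 5-fold cross-validated MSE, and within-person
partial-dependence similarity across scans.

A synthetic cohort generator (`cohort_config()` / `simulate_cohort()`)
plants all of this — adherence decay and biweekly modulation, geometric
dropout implying 153-day (adult) vs 77-day (child) median retention,
watch–survey coupling, group score differences, alert prevalence, and
smooth pre-scan physiological drifts with configurable shape and
missing-not-at-random missingness.

## Worked example

```r
library(scanwear)

cohort <- simulate_cohort(cohort_config(seed = 11))

rec <- survival_records(cohort$daily, cohort$participants, modality = "watch")
km_fit(rec, stratum = "age_group")
#> Kaplan-Meier retention fit
#>  stratum  n median iqr_lower iqr_upper median_ci_lower median_ci_upper
#>    adult 36    158        67     179.5              90             179
#>    child  9     58        29     154.0               5             165

lr <- log_rank(rec, "age_group")
sprintf("log-rank chi-square(%d) = %.2f, p = %.3f", lr$df, lr$chisq, lr$p_value)
#> "log-rank chi-square(1) = 5.50, p = 0.019"

summ <- engagement_summary(cohort$daily)
m <- merge(summ, cohort$participants, by = "participant_id")
w <- m[m$modality == "watch", ]
welch_t(w$rate[w$age_group == "adult"], w$rate[w$age_group == "child"])
#> Welch two-sample t test: t(8.9) = 0.840, p = 0.423
#>   group means 0.714 vs 0.624 (SD 0.150 vs 0.314; n = 36 vs 9)

spec <- cohort_spectra(cohort$daily)
top1 <- subset(spec$dominant, rank == 1 & modality == "watch")
median(top1$period_days)
#> 14.5
```

Reading: in this draw adults stay engaged for a median of 158 days versus
58 for children, a significant retention gap (p = .019), while the overall
percent-days-worn difference (71% vs 62%) is not significant at n = 9
children — retention and rate capture different aspects of engagement. The
median dominant engagement period of ~2 weeks reflects the planted biweekly
check-in cycle. Everything above is also available end to end:

```r
run_pipeline("all", run_config(cohort = cohort_config(), out_dir = "out", seed = 11))
```

writes the cohort CSVs, per-stage tables (`engagement_summary.csv`,
`survival_records.csv`, `km_curves.csv`, `dominant_periods.csv`,
`scores.csv`, `alerts.csv`, `gam_fit_<scan>.json`, `pdp_similarity.csv`,
…), a run manifest, and a markdown report.

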