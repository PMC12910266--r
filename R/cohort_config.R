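#' Configuration for the synthetic surveillance cohort
#'
#' Builds the parameter set that drives every stage of the synthetic cohort
#' generator: cohort composition, wear/survey adherence dynamics, dropout,
#' scan scheduling, the planted pre-scan physiological effect, instrument
#' score distributions and the self-harm alert prevalence. Defaults emulate a
#' hereditary-cancer (Li-Fraumeni) clinic cohort of 9 children and 36 adults
#' followed for 180 days with biweekly check-in calls.
#'
#' Adherence on study day `t` (0-based) is
#' `base * 2^(-t / adherence_decay_halflife_days) *
#'  (1 + checkin_modulation * sin(2 * pi * t / checkin_period_days))`,
#' clamped to `[0, 1]`, where `base` is the age-group wear adherence mean.
#' Dropout is geometric with a per-day hazard; the default hazards are chosen
#' so the implied median retention is 153 days for adults and 77 days for
#' children (the planted truths recovered by the retention module).
#'
#' @param n_children,n_adults Number of participants per age group.
#' @param prop_tp53_mut_adults Fraction of adults carrying a pathogenic TP53
#'   variant. All synthetic children are carriers unless
#'   `prop_tp53_mut_children` is lowered (child noncarriers are generatable
#'   for confounding diagnostics even though rare in clinic populations).
#' @param prop_tp53_mut_children Fraction of children carrying the variant.
#' @param prop_cancer_history Fraction of participants with a prior cancer.
#' @param horizon_days Target follow-up, days (default 180).
#' @param checkin_period_days Period of the adherence sinusoid, days
#'   (biweekly check-in calls; default 14).
#' @param checkin_modulation Relative amplitude of the adherence sinusoid.
#' @param wear_adherence_mean_adult,wear_adherence_mean_child Baseline
#'   probability that a day is an active wear day (>= 6 h).
#' @param wear_adherence_sd_adult,wear_adherence_sd_child Between-person SD
#'   of the individual adherence baseline (set 0 for a homogeneous cohort).
#' @param survey_adherence_sd Between-person SD of the survey baseline.
#' @param adherence_decay_halflife_days Half-life of the engagement decline,
#'   days.
#' @param dropout_hazard_adult,dropout_hazard_child Per-day probability of
#'   permanently leaving the study.
#' @param reentry_prob Optional per-day probability of re-entering after
#'   dropout (0 = absorbing dropout; positive values stress-test the
#'   day-state machine with post-gap activity).
#' @param survey_adherence_mean_adult,survey_adherence_mean_child Baseline
#'   daily stress-survey completion probabilities.
#' @param survey_watch_coupling Coupling in `[-1, 1]` between same-day watch
#'   activity and survey completion.
#' @param stress_very_prob_child,stress_very_prob_adult Probability that a
#'   completed daily survey reports the top ("very stressed") level.
#' @param scan_interval_days Days between surveillance scans for scanned
#'   participants.
#' @param scan_participation Fraction of participants undergoing surveillance
#'   imaging during follow-up.
#' @param prescan_effect_amplitude Named numeric, one amplitude per channel
#'   (`eda`, `heart_rate`, `hrv`, `resp_rate`, `temperature`). EDA and HRV
#'   amplitudes act on the log scale.
#' @param prescan_effect_shape One of `"flat"`, `"linear"`, `"quadratic"`,
#'   `"sigmoid"` — shape of the planted physiological drift toward the scan.
#' @param prescan_window_days Days before a scan over which the planted
#'   effect (and minute-level sampling) is active.
#' @param missing_rate Per-value probability that a physiological sample is
#'   missing.
#' @param missing_near_scan_boost Relative inflation of `missing_rate` at the
#'   scan itself (linear in scan proximity); models missingness that is not
#'   at random.
#' @param wear_hours_mean_adult,wear_hours_mean_child Mean wear hours on
#'   active days.
#' @param wear_hours_sd_between,wear_hours_sd_within Between-person and
#'   day-to-day SD of wear hours on active days.
#' @param sleep_fraction Mean fraction of wear minutes occurring during the
#'   nominal 23:00-07:00 sleep window.
#' @param instrument_period_days Days between questionnaire administrations.
#' @param phq9_mean_child,phq9_mean_adult,phq9_sd_child,phq9_sd_adult PHQ-9
#'   total-score distribution per group.
#' @param promis_mean_child,promis_mean_adult,promis_sd PROMIS
#'   sleep-related-impairment raw-sum distribution.
#' @param gad7_mean_child,gad7_mean_adult,gad7_sd GAD-7 total distribution.
#' @param pss4_mean_child,pss4_mean_adult,pss4_sd PSS-4 total distribution.
#' @param alert_item9_prob Probability that a participant ever responds
#'   positively to PHQ-9 item 9 (self-harm) during follow-up.
#' @param seed Integer seed; a fixed seed makes generated tables
#'   byte-identical across runs.
#'
#' @return An object of class `cohort_config` (a validated named list).
#' @examples
#' cfg <- cohort_config(n_children = 2, n_adults = 3, seed = 1)
#' cfg$horizon_days
#' @export
cohort_config <- function(n_children = 9,
                          n_adults = 36,
                          prop_tp53_mut_adults = 26 / 36,
                          prop_tp53_mut_children = 1,
                          prop_cancer_history = 14 / 45,
                          horizon_days = 180,
                          checkin_period_days = 14,
                          checkin_modulation = 0.25,
                          wear_adherence_mean_adult = 0.81,
                          wear_adherence_mean_child = 0.56,
                          wear_adherence_sd_adult = 0.19,
                          wear_adherence_sd_child = 0.26,
                          survey_adherence_sd = 0.22,
                          adherence_decay_halflife_days = 540,
                          dropout_hazard_adult = 1 - 2^(-1 / 153),
                          dropout_hazard_child = 1 - 2^(-1 / 77),
                          reentry_prob = 0,
                          survey_adherence_mean_adult = 0.65,
                          survey_adherence_mean_child = 0.51,
                          survey_watch_coupling = 0.7,
                          stress_very_prob_child = 0.363,
                          stress_very_prob_adult = 0.143,
                          scan_interval_days = 90,
                          scan_participation = 17 / 45,
                          prescan_effect_amplitude = c(eda = 0.5, heart_rate = 5,
                                                       hrv = -0.3, resp_rate = 1.5,
                                                       temperature = 0.4),
                          prescan_effect_shape = "quadratic",
                          prescan_window_days = 3,
                          missing_rate = 0.10,
                          missing_near_scan_boost = 0,
                          wear_hours_mean_adult = 17.6,
                          wear_hours_mean_child = 15.7,
                          wear_hours_sd_between = 2.5,
                          wear_hours_sd_within = 1.5,
                          sleep_fraction = 0.25,
                          instrument_period_days = 14,
                          phq9_mean_child = 10.0,
                          phq9_mean_adult = 4.2,
                          phq9_sd_child = 5.2,
                          phq9_sd_adult = 4.4,
                          promis_mean_child = 22.7,
                          promis_mean_adult = 16.5,
                          promis_sd = 5.7,
                          gad7_mean_child = 6.0,
                          gad7_mean_adult = 5.0,
                          gad7_sd = 4.0,
                          pss4_mean_child = 7.0,
                          pss4_mean_adult = 6.0,
                          pss4_sd = 3.0,
                          alert_item9_prob = 0.11,
                          seed = NULL) {
  cfg <- as.list(environment())
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  stop_cfg <- function(msg) stop("invalid cohort_config: ", msg, call. = FALSE)
  counts <- c("n_children", "n_adults", "horizon_days", "checkin_period_days",
              "scan_interval_days", "prescan_window_days",
              "instrument_period_days")
  for (f in counts) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v != round(v))
      stop_cfg(paste0(f, " must be a non-negative integer"))
  }
  if (cfg$horizon_days < 1) stop_cfg("horizon_days must be >= 1")
  fracs <- c("prop_tp53_mut_adults", "prop_tp53_mut_children",
             "prop_cancer_history", "wear_adherence_mean_adult",
             "wear_adherence_mean_child", "dropout_hazard_adult",
             "dropout_hazard_child", "reentry_prob",
             "survey_adherence_mean_adult", "survey_adherence_mean_child",
             "stress_very_prob_child", "stress_very_prob_adult",
             "scan_participation", "missing_rate", "sleep_fraction",
             "alert_item9_prob")
  for (f in fracs) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)
      stop_cfg(paste0(f, " must be a fraction in [0, 1]"))
  }
  if (abs(cfg$survey_watch_coupling) > 1)
    stop_cfg("survey_watch_coupling must lie in [-1, 1]")
  if (!is.numeric(cfg$adherence_decay_halflife_days) ||
      cfg$adherence_decay_halflife_days <= 0)
    stop_cfg("adherence_decay_halflife_days must be positive")
  if (!cfg$prescan_effect_shape %in% c("flat", "linear", "quadratic", "sigmoid"))
    stop_cfg("prescan_effect_shape must be flat/linear/quadratic/sigmoid")
  need <- c("eda", "heart_rate", "hrv", "resp_rate", "temperature")
  if (!all(need %in% names(cfg$prescan_effect_amplitude)))
    stop_cfg("prescan_effect_amplitude must name all five channels")
  sds <- c("phq9_sd_child", "phq9_sd_adult", "promis_sd", "gad7_sd", "pss4_sd",
           "wear_hours_sd_between", "wear_hours_sd_within")
  for (f in sds) if (cfg[[f]] < 0) stop_cfg(paste0(f, " must be non-negative"))
  if (cfg$wear_hours_sd_within <= 0)
    stop_cfg("wear_hours_sd_within must be positive")
  het <- c("wear_adherence_sd_adult", "wear_adherence_sd_child",
           "survey_adherence_sd")
  for (f in het) if (cfg[[f]] < 0 || cfg[[f]] > 1)
    stop_cfg(paste0(f, " must lie in [0, 1]"))
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  participants : %d children + %d adults, horizon %d days\n",
              x$n_children, x$n_adults, x$horizon_days))
  cat(sprintf("  wear adherence (adult/child): %.2f / %.2f, half-life %g d, check-in period %d d\n",
              x$wear_adherence_mean_adult, x$wear_adherence_mean_child,
              x$adherence_decay_halflife_days, x$checkin_period_days))
  cat(sprintf("  dropout hazard (adult/child): %.4f / %.4f per day\n",
              x$dropout_hazard_adult, x$dropout_hazard_child))
  cat(sprintf("  scans every %d d for %.0f%% of cohort; pre-scan effect '%s' over %d d\n",
              x$scan_interval_days, 100 * x$scan_participation,
              x$prescan_effect_shape, x$prescan_window_days))
  cat(sprintf("  seed: %s\n", if (is.null(x$seed)) "<none>" else x$seed))
  invisible(x)
}

# Planted per-day probability of an active wear day (the generator's ground
# truth; exported so recovery tests can use it as an oracle).

#' Planted daily adherence probabilities
#'
#' The exact per-day Bernoulli probability of an active day used by
#' [simulate_wear()] — baseline times exponential decay times check-in
#' sinusoid, clamped to `[0, 1]`. Useful as the ground-truth oracle when
#' checking that downstream estimators recover planted structure.
#'
#' @param age_group `"child"` or `"adult"`.
#' @param config A [cohort_config()].
#' @param what `"wear"` or `"survey"` baseline.
#' @return Numeric vector of length `horizon_days`.
#' @export
adherence_probability <- function(age_group, config, what = c("wear", "survey")) {
  what <- match.arg(what)
  base <- if (what == "wear") {
    if (age_group == "child") config$wear_adherence_mean_child else config$wear_adherence_mean_adult
  } else {
    if (age_group == "child") config$survey_adherence_mean_child else config$survey_adherence_mean_adult
  }
  t <- seq_len(config$horizon_days) - 1
  p <- base * 2^(-t / config$adherence_decay_halflife_days) *
    (1 + config$checkin_modulation * sin(2 * pi * t / config$checkin_period_days))
  pmin(pmax(p, 0), 1)
}
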