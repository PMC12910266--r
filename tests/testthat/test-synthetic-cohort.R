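test_that("generate_cohort matches configured composition and is deterministic", {
  cfg <- cohort_config(n_children = 9, n_adults = 36, seed = 3)
  p <- generate_cohort(cfg)
  expect_equal(nrow(p), 45)
  expect_equal(sum(p$age_group == "child"), 9)
  expect_equal(sum(p$age_group == "adult"), 36)
  # children are all carriers by default; adult carriers within rounding
  expect_true(all(p$tp53_status[p$age_group == "child"] == "mut"))
  expect_equal(sum(p$tp53_status == "mut" & p$age_group == "adult"),
               round(36 * cfg$prop_tp53_mut_adults))
  expect_equal(sum(p$cancer_history), round(45 * cfg$prop_cancer_history))
  expect_true(all((p$age_years < 18) == (p$age_group == "child")))
  expect_identical(p, generate_cohort(cfg))

  one <- generate_cohort(cohort_config(n_children = 0, n_adults = 1, seed = 1))
  expect_equal(nrow(one), 1)
  expect_equal(one$age_group, "adult")
})

test_that("cohort_config rejects invalid parameters", {
  expect_error(cohort_config(n_children = -1), "non-negative")
  expect_error(cohort_config(missing_rate = 1.2), "fraction")
  expect_error(cohort_config(horizon_days = 0), "horizon_days")
  expect_error(cohort_config(survey_watch_coupling = 1.5), "coupling")
  expect_error(cohort_config(prescan_effect_shape = "cubic"), "shape")
})

test_that("simulate_wear respects range invariants and saturates correctly", {
  cfg <- cohort_config(n_children = 0, n_adults = 1,
                       dropout_hazard_adult = 0,
                       adherence_decay_halflife_days = 1e9,
                       wear_adherence_mean_adult = 1,
                       wear_adherence_sd_adult = 0,
                       checkin_modulation = 0, seed = 5)
  p <- generate_cohort(cfg)[1, ]
  w <- simulate_wear(p, cfg)
  expect_equal(nrow(w), 180)
  expect_true(all(w$valid_wear_minutes >= 360)) # saturated adherence
  expect_true(all(w$valid_wear_minutes <= 1440))
  expect_identical(w$sleep_wear_minutes + w$awake_wear_minutes,
                   w$valid_wear_minutes)
  expect_true(all(w$sleep_wear_minutes <= 480))
})

test_that("planted check-in periodicity shows as an autocorrelation peak at lag 14", {
  cfg <- cohort_config(n_children = 0, n_adults = 1, horizon_days = 10000,
                       dropout_hazard_adult = 0,
                       adherence_decay_halflife_days = 1e9,
                       wear_adherence_mean_adult = 0.6,
                       wear_adherence_sd_adult = 0,
                       checkin_modulation = 0.4,
                       checkin_period_days = 14, seed = 8)
  p <- generate_cohort(cfg)[1, ]
  active <- simulate_wear(p, cfg)$valid_wear_minutes >= 360
  ac <- stats::acf(as.numeric(active), lag.max = 20, plot = FALSE)$acf[-1]
  # empirical peak within one lag of the planted period, well above noise
  expect_true(which.max(ac) %in% 13:15)
  expect_gt(ac[14], 4 / sqrt(length(active)))
  # oracle: the planted Bernoulli probabilities share the same peak
  p_t <- adherence_probability("adult", cfg, "wear")
  ac_p <- stats::acf(p_t, lag.max = 20, plot = FALSE)$acf[-1]
  expect_equal(which.max(ac_p), 14)
})

test_that("adult-child adherence gap is recovered against the planted oracle", {
  cfg <- cohort_config(n_children = 100, n_adults = 100,
                       dropout_hazard_adult = 0, dropout_hazard_child = 0,
                       seed = 13)
  cohort <- simulate_cohort(cfg)
  summ <- engagement_summary(cohort$daily, denominator = "observed")
  m <- merge(summ[summ$modality == "watch", ], cohort$participants)
  gap <- mean(m$rate[m$age_group == "adult"]) -
    mean(m$rate[m$age_group == "child"])
  # oracle: mean planted probability gap (no dropout, observed span = horizon);
  # tolerance ~3 SE of the gap under the between-person adherence SDs
  oracle_gap <- mean(adherence_probability("adult", cfg, "wear")) -
    mean(adherence_probability("child", cfg, "wear"))
  gap_se <- sqrt(cfg$wear_adherence_sd_adult^2 / 100 +
                   cfg$wear_adherence_sd_child^2 / 100)
  expect_lt(abs(gap - oracle_gap), 3 * gap_se)
  expect_gt(gap, 0.15)
})

test_that("survey coupling and stress levels follow the configuration", {
  # coupling = 0: independent completion
  cfg0 <- cohort_config(n_children = 0, n_adults = 1, horizon_days = 10000,
                        dropout_hazard_adult = 0, survey_watch_coupling = 0,
                        adherence_decay_halflife_days = 1e9,
                        checkin_modulation = 0, seed = 2)
  p <- generate_cohort(cfg0)[1, ]
  w <- simulate_wear(p, cfg0)
  s <- simulate_surveys(p, w, cfg0)
  r0 <- cor(as.numeric(w$valid_wear_minutes >= 360), as.numeric(s$completed))
  expect_lt(abs(r0), 0.05)

  # coupling = 0.7: smoothed series strongly correlated across the cohort
  cfg <- cohort_config(n_children = 0, n_adults = 100,
                       survey_watch_coupling = 0.7, seed = 4)
  cohort <- simulate_cohort(cfg)
  summ <- engagement_summary(cohort$daily)
  r <- summ$coupling_r[summ$modality == "watch"]
  expect_gt(median(r, na.rm = TRUE), 0.5)

  # child very-stressed frequency near the planted 36.3%
  cfgc <- cohort_config(n_children = 1, n_adults = 0, horizon_days = 5000,
                        dropout_hazard_child = 0,
                        adherence_decay_halflife_days = 1e9, seed = 6)
  pc <- generate_cohort(cfgc)[1, ]
  wc <- simulate_wear(pc, cfgc)
  sc <- simulate_surveys(pc, wc, cfgc)
  f <- stress_frequency(sc$completed, sc$stress_level)
  expect_lt(abs(f - 0.363), 0.03)
})

test_that("simulate_physio plants effects, positivity and missingness as configured", {
  base_cfg <- function(...) cohort_config(
    n_children = 0, n_adults = 1, dropout_hazard_adult = 0,
    wear_adherence_mean_adult = 1, wear_adherence_sd_adult = 0,
    checkin_modulation = 0,
    adherence_decay_halflife_days = 1e9, scan_participation = 1, seed = 9, ...)

  # null effect: channel means equal baseline within noise SE
  cfg <- base_cfg(prescan_effect_amplitude = c(eda = 0, heart_rate = 0, hrv = 0,
                                               resp_rate = 0, temperature = 0),
                  missing_rate = 0)
  p <- generate_cohort(cfg)[1, ]
  w <- simulate_wear(p, cfg)
  sc <- data.frame(participant_id = p$participant_id, scan_day = c(30L, 90L),
                   modality = "MRI")
  ph <- simulate_physio(p, sc, w, cfg)
  expect_false(anyNA(ph))
  expect_true(all(ph$eda > 0) && all(ph$hrv > 0))
  # flat effect: first vs last pre-scan day means agree within noise SE
  d1 <- ph$timestamp_min < 28 * 1440
  se <- sd(ph$heart_rate) * sqrt(1 / sum(d1) + 1 / sum(!d1))
  expect_lt(abs(mean(ph$heart_rate[d1]) - mean(ph$heart_rate[!d1])), 4 * se)

  # configured missingness rate is realized
  cfg2 <- base_cfg(missing_rate = 0.3)
  p2 <- generate_cohort(cfg2)[1, ]
  w2 <- simulate_wear(p2, cfg2)
  ph2 <- simulate_physio(p2, sc, w2, cfg2)
  expect_lt(abs(mean(is.na(ph2$eda)) - 0.3), 0.02)
})

test_that("instrument generator obeys ranges and the alert probability", {
  cfg <- cohort_config(n_children = 5, n_adults = 5, alert_item9_prob = 0,
                       seed = 10)
  cohort <- simulate_cohort(cfg)
  iv <- cohort$instruments
  # legal item ranges per instrument
  spec <- list(PHQ9 = c(0, 3), GAD7 = c(0, 3), PSS4 = c(0, 4),
               PROMIS_SRI = c(1, 5))
  for (inst in names(spec)) {
    v <- iv$value[iv$instrument == inst]
    expect_true(all(v >= spec[[inst]][1] & v <= spec[[inst]][2]))
  }
  expect_true(all(iv$value[iv$instrument == "PHQ9" & iv$item_index == 9] == 0))

  cfg1 <- cohort_config(n_children = 5, n_adults = 5, alert_item9_prob = 1,
                        seed = 10)
  iv1 <- simulate_cohort(cfg1)$instruments
  pos <- iv1[iv1$instrument == "PHQ9" & iv1$item_index == 9 & iv1$value > 0, ]
  expect_equal(sort(unique(pos$participant_id)),
               sort(unique(iv1$participant_id))) # everyone alerts once
  expect_equal(nrow(pos), length(unique(iv1$participant_id)))
})

test_that("a fixed seed makes the whole cohort byte-identical", {
  a <- simulate_cohort(cohort_config(n_children = 2, n_adults = 3, seed = 99))
  b <- simulate_cohort(cohort_config(n_children = 2, n_adults = 3, seed = 99))
  for (nm in c("participants", "daily", "scans", "physio", "instruments")) {
    expect_identical(a[[nm]], b[[nm]])
  }
})
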