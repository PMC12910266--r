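#' Generate the participant table of a synthetic cohort
#'
#' Draws `n_children + n_adults` participants with age, TP53 carrier status,
#' cancer history and a rolling enrollment date. Carrier and cancer-history
#' counts are assigned exactly (rounded from the configured proportions) so
#' stratum composition matches the configuration within integer rounding.
#'
#' @param config A [cohort_config()]. If `config$seed` is non-`NULL` the RNG
#'   is seeded, making the table deterministic.
#' @return A data.frame with columns `participant_id`, `age_group`
#'   (`"child"`/`"adult"`), `age_years`, `tp53_status` (`"wt"`/`"mut"`),
#'   `cancer_history` (logical), `enrollment_day` (Date).
#' @examples
#' head(generate_cohort(cohort_config(n_children = 2, n_adults = 3, seed = 1)))
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_children + config$n_adults
  if (n == 0) {
    return(data.frame(participant_id = character(), age_group = character(),
                      age_years = numeric(), tp53_status = character(),
                      cancer_history = logical(),
                      enrollment_day = as.Date(character())))
  }
  age_group <- c(rep("child", config$n_children), rep("adult", config$n_adults))
  age_years <- ifelse(age_group == "child",
                      runif(n, 6, 17.99),
                      runif(n, 18.1, 70))
  assign_exact <- function(n_grp, prop) {
    k <- round(n_grp * prop)
    sample(c(rep(TRUE, k), rep(FALSE, n_grp - k)))
  }
  mut <- logical(n)
  mut[age_group == "child"] <- assign_exact(config$n_children,
                                            config$prop_tp53_mut_children)
  mut[age_group == "adult"] <- assign_exact(config$n_adults,
                                            config$prop_tp53_mut_adults)
  cancer <- assign_exact(n, config$prop_cancer_history)
  # rolling 6-month enrollment window
  enroll <- as.Date("2022-01-01") + sample(0:180, n, replace = TRUE)
  data.frame(
    participant_id = sprintf("P%03d", seq_len(n)),
    age_group = age_group,
    age_years = round(age_years, 1),
    tp53_status = ifelse(mut, "mut", "wt"),
    cancer_history = cancer,
    enrollment_day = enroll,
    stringsAsFactors = FALSE
  )
}

# number of observed on-study days before (absorbing) dropout
draw_enrolled_days <- function(hazard, horizon, reentry_prob = 0) {
  if (hazard <= 0) return(rep(TRUE, horizon))
  if (reentry_prob <= 0) {
    n_obs <- min(horizon, 1 + rgeom(1, hazard))
    return(seq_len(horizon) <= n_obs)
  }
  # two-state Markov chain enrolled <-> dropped, for state-machine stress tests
  enrolled <- logical(horizon)
  state <- TRUE
  for (t in seq_len(horizon)) {
    enrolled[t] <- state
    state <- if (state) runif(1) >= hazard else runif(1) < reentry_prob
  }
  enrolled
}

#' Simulate daily smartwatch wear for one participant
#'
#' Each on-study day is an "active" wear day with the planted probability
#' from [adherence_probability()] (baseline x decay x check-in sinusoid).
#' Active days draw wear hours around the group mean; nonactive days draw a
#' short or zero wear time. Wear minutes are split into a sleep component
#' (the nominal 23:00-07:00 window, capped at 480 min) and an awake
#' remainder. After the geometric dropout day no further records are
#' emitted, so the returned series has at most `horizon_days` rows.
#'
#' @param participant One row of [generate_cohort()] output.
#' @param config A [cohort_config()].
#' @return A data.frame `participant_id`, `day_index` (0-based),
#'   `valid_wear_minutes`, `sleep_wear_minutes`, `awake_wear_minutes`.
#' @export
simulate_wear <- function(participant, config) {
  h <- config$horizon_days
  child <- participant$age_group == "child"
  hazard <- if (child) config$dropout_hazard_child else config$dropout_hazard_adult
  enrolled <- draw_enrolled_days(hazard, h, config$reentry_prob)
  days <- which(enrolled) - 1L
  n <- length(days)
  if (n == 0) {
    return(data.frame(participant_id = character(), day_index = integer(),
                      valid_wear_minutes = integer(),
                      sleep_wear_minutes = integer(),
                      awake_wear_minutes = integer()))
  }
  base <- if (child) config$wear_adherence_mean_child else config$wear_adherence_mean_adult
  sd_adh <- if (child) config$wear_adherence_sd_child else config$wear_adherence_sd_adult
  # individual adherence baseline (between-person heterogeneity)
  ind_base <- min(max(rnorm(1, base, sd_adh), 0.02), 0.98)
  p_pop <- adherence_probability(participant$age_group, config, "wear")[days + 1]
  p <- if (sd_adh == 0 || base <= 0) p_pop else
    pmin(pmax(p_pop * ind_base / base, 0), 1)
  active <- runif(n) < p
  mean_min <- 60 * (if (child) config$wear_hours_mean_child else config$wear_hours_mean_adult)
  ind_mean <- min(max(rnorm(1, mean_min, 60 * config$wear_hours_sd_between),
                      390), 1380)
  wear <- integer(n)
  wear[active] <- as.integer(pmin(1440, pmax(360,
    round(rnorm(sum(active), ind_mean, 60 * config$wear_hours_sd_within)))))
  n_in <- sum(!active)
  if (n_in > 0) {
    zero <- runif(n_in) < 0.4
    w <- round(runif(n_in, 0, 359))
    w[zero] <- 0
    wear[!active] <- as.integer(w)
  }
  ind_sf <- min(max(rnorm(1, config$sleep_fraction, 0.08), 0.05), 0.5)
  sf <- pmin(pmax(rnorm(n, ind_sf, 0.04), 0), 1)
  sleep <- as.integer(pmin(round(wear * sf), 480L, wear))
  data.frame(
    participant_id = rep(participant$participant_id, n),
    day_index = days,
    valid_wear_minutes = wear,
    sleep_wear_minutes = sleep,
    awake_wear_minutes = wear - sleep,
    stringsAsFactors = FALSE
  )
}

#' Simulate daily stress-survey completion for one participant
#'
#' Completion probability is the survey adherence curve shifted by
#' `survey_watch_coupling * (watch_active - p_watch)` on the same day, which
#' plants a positive (or negative) correlation between same-day watch and
#' survey activity. Completed days carry an ordinal stress level 0-3 whose
#' top level ("very stressed") has the configured age-group probability.
#'
#' @param participant One row of [generate_cohort()] output.
#' @param wear_series Output of [simulate_wear()] for the same participant.
#' @param config A [cohort_config()].
#' @return A data.frame `participant_id`, `day_index`, `completed` (logical),
#'   `stress_level` (integer 0-3, `NA` when not completed).
#' @export
simulate_surveys <- function(participant, wear_series, config) {
  n <- nrow(wear_series)
  if (n == 0) {
    return(data.frame(participant_id = character(), day_index = integer(),
                      completed = logical(), stress_level = integer()))
  }
  child <- participant$age_group == "child"
  days <- wear_series$day_index
  p_w <- adherence_probability(participant$age_group, config, "wear")[days + 1]
  p_s <- adherence_probability(participant$age_group, config, "survey")[days + 1]
  base_s <- if (child) config$survey_adherence_mean_child else config$survey_adherence_mean_adult
  if (config$survey_adherence_sd > 0 && base_s > 0) {
    ind_s <- min(max(rnorm(1, base_s, config$survey_adherence_sd), 0.02), 0.98)
    p_s <- pmin(pmax(p_s * ind_s / base_s, 0), 1)
  }
  watch_active <- wear_series$valid_wear_minutes >= 360
  p <- pmin(pmax(p_s + config$survey_watch_coupling * (watch_active - p_w), 0), 1)
  completed <- runif(n) < p
  p_very <- if (child) config$stress_very_prob_child else config$stress_very_prob_adult
  # remaining mass split 0.3/0.4/0.3 across levels 0-2
  probs <- c((1 - p_very) * c(0.3, 0.4, 0.3), p_very)
  stress <- rep(NA_integer_, n)
  k <- sum(completed)
  if (k > 0) stress[completed] <- sample(0:3, k, replace = TRUE, prob = probs)
  data.frame(
    participant_id = rep(participant$participant_id, n),
    day_index = days,
    completed = completed,
    stress_level = stress,
    stringsAsFactors = FALSE
  )
}

#' Simulate surveillance scan events for one participant
#'
#' A configured fraction of participants undergoes imaging at regular
#' intervals (with a few days of jitter) from enrollment to the horizon.
#'
#' @param participant One row of [generate_cohort()] output.
#' @param config A [cohort_config()].
#' @return A data.frame `participant_id`, `scan_day`, `modality`.
#' @export
simulate_scans <- function(participant, config) {
  empty <- data.frame(participant_id = character(), scan_day = integer(),
                      modality = character(), stringsAsFactors = FALSE)
  if (runif(1) >= config$scan_participation) return(empty)
  base_days <- seq(config$scan_interval_days, config$horizon_days,
                   by = config$scan_interval_days)
  if (length(base_days) == 0) return(empty)
  days <- pmin(pmax(base_days + sample(-7:7, length(base_days), replace = TRUE), 1),
               config$horizon_days)
  days <- sort(unique(days))
  data.frame(
    participant_id = rep(participant$participant_id, length(days)),
    scan_day = as.integer(days),
    modality = sample(c("MRI", "ultrasound"), length(days), replace = TRUE,
                      prob = c(0.7, 0.3)),
    stringsAsFactors = FALSE
  )
}

# planted pre-scan drift, normalized to [0, 1] over the window;
# u = 0 at window start, u = 1 at the scan
prescan_shape <- function(u, shape) {
  switch(shape,
         flat = rep(0, length(u)),
         linear = u,
         quadratic = u^2,
         sigmoid = 1 / (1 + exp(-10 * (u - 0.5))),
         stop("unknown prescan_effect_shape: ", shape))
}

#' Planted pre-scan effect evaluated on a grid
#'
#' Ground-truth drift `amplitude * g(u)` added to a channel within the
#' pre-scan window, where `u` runs from 0 (window start) to 1 (scan time).
#' Exported as the oracle for partial-dependence recovery tests.
#'
#' @param u Numeric in `[0, 1]`, scan proximity.
#' @param shape `"flat"`, `"linear"`, `"quadratic"` or `"sigmoid"`.
#' @param amplitude Effect amplitude.
#' @return Numeric vector, the planted drift.
#' @export
prescan_effect <- function(u, shape, amplitude = 1) {
  amplitude * prescan_shape(u, shape)
}

#' Simulate minute-level physiology around scans for one participant
#'
#' Emits one sample per worn minute inside the pre-scan window of each scan
#' (`prescan_window_days` before the scan, half-open at the scan minute,
#' which is midnight of `scan_day`). Each channel is an individual baseline
#' plus the planted drift [prescan_effect()] plus Gaussian noise; EDA and
#' HRV are generated on the log scale so they stay strictly positive.
#' Overlapping pre-scan windows have their planted effects summed. Every
#' value is independently missing with probability `missing_rate`, optionally
#' inflated linearly toward the scan by `missing_near_scan_boost` (a
#' missing-not-at-random mechanism).
#'
#' @param participant One row of [generate_cohort()] output.
#' @param scans Output of [simulate_scans()] (sorted by `scan_day`).
#' @param wear_series Output of [simulate_wear()]; samples exist only for
#'   worn minutes.
#' @param config A [cohort_config()].
#' @return A data.frame `participant_id`, `timestamp_min` (minutes since
#'   enrollment midnight), `eda`, `heart_rate`, `hrv`, `resp_rate`,
#'   `temperature` (`NA` where missing).
#' @export
simulate_physio <- function(participant, scans, wear_series, config) {
  empty <- data.frame(participant_id = character(), timestamp_min = integer(),
                      eda = numeric(), heart_rate = numeric(), hrv = numeric(),
                      resp_rate = numeric(), temperature = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(scans) == 0 || nrow(wear_series) == 0) return(empty)
  w_min <- config$prescan_window_days * 1440L
  # worn minutes: the first valid_wear_minutes minutes of each worn day
  worn <- unlist(lapply(seq_len(nrow(wear_series)), function(i) {
    v <- wear_series$valid_wear_minutes[i]
    if (v <= 0) return(integer())
    wear_series$day_index[i] * 1440L + seq_len(v) - 1L
  }))
  if (length(worn) == 0) return(empty)
  scan_min <- scans$scan_day * 1440L
  in_any <- rep(FALSE, length(worn))
  effect_u <- rep(0, length(worn)) # summed shape over overlapping windows
  for (s in scan_min) {
    sel <- worn >= (s - w_min) & worn < s
    if (!any(sel)) next
    in_any <- in_any | sel
    u <- 1 - (s - worn[sel]) / w_min
    effect_u[sel] <- effect_u[sel] + prescan_shape(u, config$prescan_effect_shape)
  }
  worn <- worn[in_any]
  eff <- effect_u[in_any]
  n <- length(worn)
  if (n == 0) return(empty)
  amp <- config$prescan_effect_amplitude
  # individual baselines
  b_eda <- exp(rnorm(1, log(1.5), 0.4))
  b_hr <- rnorm(1, 75, 6)
  b_hrv <- exp(rnorm(1, log(50), 0.3))
  b_rr <- rnorm(1, 16, 1.5)
  b_tp <- rnorm(1, 33, 0.7)
  eda <- exp(log(b_eda) + amp[["eda"]] * eff + rnorm(n, 0, 0.3))
  hr <- b_hr + amp[["heart_rate"]] * eff + rnorm(n, 0, 4)
  hrv <- exp(log(b_hrv) + amp[["hrv"]] * eff + rnorm(n, 0, 0.25))
  rr <- b_rr + amp[["resp_rate"]] * eff + rnorm(n, 0, 1.2)
  tp <- b_tp + amp[["temperature"]] * eff + rnorm(n, 0, 0.5)
  out <- data.frame(
    participant_id = rep(participant$participant_id, n),
    timestamp_min = worn,
    eda = eda, heart_rate = hr, hrv = hrv, resp_rate = rr, temperature = tp,
    stringsAsFactors = FALSE
  )
  if (config$missing_rate > 0 || config$missing_near_scan_boost > 0) {
    # proximity to the nearest upcoming scan drives the optional MNAR boost
    u_near <- rep(0, n)
    for (s in scan_min) {
      sel <- worn >= (s - w_min) & worn < s
      u_near[sel] <- pmax(u_near[sel], 1 - (s - worn[sel]) / w_min)
    }
    p_miss <- pmin(config$missing_rate * (1 + config$missing_near_scan_boost * u_near),
                   0.95)
    for (ch in c("eda", "heart_rate", "hrv", "resp_rate", "temperature")) {
      out[[ch]][runif(n) < p_miss] <- NA_real_
    }
  }
  out
}

instrument_spec <- function() {
  list(
    PHQ9 = list(n_items = 9, min = 0, max = 3, reverse = integer()),
    GAD7 = list(n_items = 7, min = 0, max = 3, reverse = integer()),
    PSS4 = list(n_items = 4, min = 0, max = 4, reverse = c(2L, 3L)),
    PROMIS_SRI = list(n_items = 8, min = 1, max = 5, reverse = integer())
  )
}

# distribute a target total over items, each in [min, max]; reverse-scored
# items are stored raw (max - scored value)
distribute_items <- function(total, spec) {
  k <- spec$n_items
  lo <- spec$min * k
  hi <- spec$max * k
  total <- max(lo, min(hi, round(total)))
  scored <- rep(spec$min, k)
  left <- total - lo
  while (left > 0) {
    open <- which(scored < spec$max)
    i <- if (length(open) == 1) open else sample(open, 1)
    scored[i] <- scored[i] + 1
    left <- left - 1
  }
  raw <- scored
  if (length(spec$reverse) > 0)
    raw[spec$reverse] <- (spec$max + spec$min) - scored[spec$reverse]
  raw
}

#' Simulate periodic questionnaire responses for one participant
#'
#' Administers PHQ-9, GAD-7, PSS-4 and PROMIS sleep-related-impairment every
#' `instrument_period_days` from day 0 while the participant is on study.
#' Totals are drawn around the configured age-group mean/SD, truncated to the
#' instrument's legal range, and decomposed into item responses (PSS-4 items
#' 2 and 3 are stored raw, i.e. before reverse scoring). With probability
#' `alert_item9_prob` a participant is an "alerter": exactly one of their
#' PHQ-9 responses carries a positive item 9 (self-harm) in 1-3; all other
#' item-9 responses are 0.
#'
#' @param participant One row of [generate_cohort()] output.
#' @param wear_series Output of [simulate_wear()]; instruments are only
#'   administered up to the participant's last on-study day.
#' @param config A [cohort_config()].
#' @return Long-format data.frame `participant_id`, `day_index`,
#'   `instrument`, `item_index`, `value`.
#' @export
simulate_instruments <- function(participant, wear_series, config) {
  last_day <- if (nrow(wear_series) > 0) max(wear_series$day_index) else 0L
  days <- seq(0L, last_day, by = config$instrument_period_days)
  child <- participant$age_group == "child"
  specs <- instrument_spec()
  means <- list(
    PHQ9 = if (child) config$phq9_mean_child else config$phq9_mean_adult,
    GAD7 = if (child) config$gad7_mean_child else config$gad7_mean_adult,
    PSS4 = if (child) config$pss4_mean_child else config$pss4_mean_adult,
    PROMIS_SRI = if (child) config$promis_mean_child else config$promis_mean_adult
  )
  sds <- list(
    PHQ9 = if (child) config$phq9_sd_child else config$phq9_sd_adult,
    GAD7 = config$gad7_sd, PSS4 = config$pss4_sd, PROMIS_SRI = config$promis_sd
  )
  alerter <- runif(1) < config$alert_item9_prob
  alert_visit <- if (alerter && length(days) > 0) sample(seq_along(days), 1) else 0L
  rows <- list()
  for (vi in seq_along(days)) {
    for (inst in names(specs)) {
      spec <- specs[[inst]]
      total <- rnorm(1, means[[inst]], sds[[inst]])
      items <- distribute_items(total, spec)
      if (inst == "PHQ9") {
        items[9] <- if (vi == alert_visit) sample(1:3, 1) else 0L
      }
      rows[[length(rows) + 1]] <- data.frame(
        participant_id = participant$participant_id,
        day_index = days[vi],
        instrument = inst,
        item_index = seq_len(spec$n_items),
        value = as.integer(items),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) {
    return(data.frame(participant_id = character(), day_index = integer(),
                      instrument = character(), item_index = integer(),
                      value = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Simulate a complete synthetic cohort
#'
#' Runs every generator stage in a fixed order under a single seeded RNG
#' stream, so a fixed `config$seed` yields byte-identical tables across runs.
#'
#' @param config A [cohort_config()].
#' @return A list of data.frames: `participants`, `daily` (wear and survey
#'   merged on participant and day), `scans`, `physio`, `instruments`, plus
#'   the `config` used.
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_children = 2, n_adults = 3, seed = 7))
#' names(cohort)
#' @export
simulate_cohort <- function(config) {
  validate_cohort_config(config)
  participants <- generate_cohort(config) # seeds the RNG if config$seed set
  daily <- list(); scans <- list(); physio <- list(); instr <- list()
  for (i in seq_len(nrow(participants))) {
    p <- participants[i, ]
    wear <- simulate_wear(p, config)
    survey <- simulate_surveys(p, wear, config)
    sc <- simulate_scans(p, config)
    ph <- simulate_physio(p, sc, wear, config)
    iv <- simulate_instruments(p, wear, config)
    daily[[i]] <- merge(wear, survey, by = c("participant_id", "day_index"),
                        all = TRUE, sort = TRUE)
    scans[[i]] <- sc; physio[[i]] <- ph; instr[[i]] <- iv
  }
  bind <- function(lst, proto) {
    lst <- Filter(function(d) nrow(d) > 0, lst)
    if (length(lst) == 0) proto else do.call(rbind, lst)
  }
  list(
    participants = participants,
    daily = bind(daily, data.frame(participant_id = character(),
                                   day_index = integer(),
                                   valid_wear_minutes = integer(),
                                   sleep_wear_minutes = integer(),
                                   awake_wear_minutes = integer(),
                                   completed = logical(),
                                   stress_level = integer())),
    scans = bind(scans, data.frame(participant_id = character(),
                                   scan_day = integer(), modality = character())),
    physio = bind(physio, data.frame(participant_id = character(),
                                     timestamp_min = integer(), eda = numeric(),
                                     heart_rate = numeric(), hrv = numeric(),
                                     resp_rate = numeric(),
                                     temperature = numeric())),
    instruments = bind(instr, data.frame(participant_id = character(),
                                         day_index = integer(),
                                         instrument = character(),
                                         item_index = integer(),
                                         value = integer())),
    config = config
  )
}

#' Write a simulated cohort to delimited text files
#'
#' Writes `participants.csv`, `daily.csv`, `scans.csv`, `physio.csv`,
#' `instruments.csv` (comma-separated, header row, UTF-8) and a
#' `cohort_config.json` sidecar recording the full configuration including
#' the seed.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c()
  for (nm in c("participants", "daily", "scans", "physio", "instruments")) {
    path <- file.path(dir, paste0(nm, ".csv"))
    write.csv(cohort[[nm]], path, row.names = FALSE)
    paths <- c(paths, path)
  }
  cfg_path <- file.path(dir, "cohort_config.json")
  cfg <- cohort$config
  cfg$prescan_effect_amplitude <- as.list(cfg$prescan_effect_amplitude)
  write_json(unclass(cfg), cfg_path, auto_unbox = TRUE, null = "null",
             digits = NA)
  invisible(c(paths, cfg_path))
}
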