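test_that("classify_states applies the two-pass reclassification rule", {
  expect_equal(unclass(classify_states(c(TRUE, TRUE, TRUE))),
               rep("active", 3))
  expect_equal(unclass(classify_states(c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE))),
               c("active", "inactive", "inactive", "active", "exit", "exit"))
  expect_equal(unclass(classify_states(c(FALSE, FALSE, FALSE))),
               rep("exit", 3))
  expect_error(classify_states(logical(0)), "empty")
  # days without a record are nonactive
  expect_equal(unclass(classify_states(c(TRUE, NA, TRUE, NA))),
               c("active", "inactive", "active", "exit"))
})

test_that("exit labels are terminal and states match the brute-force oracle", {
  set.seed(4)
  for (i in 1:50) {
    active <- runif(sample(3:40, 1)) < 0.5
    s <- unclass(classify_states(active))
    expect_equal(s, oracle_states(active))
    ex <- which(s == "exit")
    if (length(ex) > 0) expect_equal(ex, seq(min(ex), length(s)))
    # appending an active day leaves no exit run
    s2 <- unclass(classify_states(c(active, TRUE)))
    expect_false(any(s2 == "exit"))
  }
})

test_that("first_sustained_exit derives event times and censoring", {
  ev <- first_sustained_exit(classify_states(c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE)))
  expect_equal(ev$time_days, 4)
  expect_true(ev$event)

  cens <- first_sustained_exit(classify_states(rep(TRUE, 180)))
  expect_equal(cens$time_days, 180)
  expect_false(cens$event)

  # exit run beginning after the horizon is censored at the horizon
  late <- c(rep(TRUE, 200), rep(FALSE, 20))
  ev2 <- first_sustained_exit(classify_states(late), horizon = 180)
  expect_equal(ev2$time_days, 180)
  expect_false(ev2$event)

  never <- first_sustained_exit(classify_states(c(FALSE, FALSE)))
  expect_equal(never$time_days, 0)
  expect_true(never$event)
})

test_that("km_fit reproduces hand-computed product-limit estimates", {
  rec <- data.frame(time_days = c(1, 2, 3), event = c(TRUE, TRUE, TRUE))
  km <- km_fit(rec)
  s <- km$curve$survival[km$curve$n_event > 0]
  expect_equal(s, c(2 / 3, 1 / 3, 0), tolerance = 1e-12)
  expect_equal(km$summary$median, 2)

  # one censored observation shrinks the risk set
  rec2 <- data.frame(time_days = c(1, 2, 3), event = c(FALSE, TRUE, TRUE))
  km2 <- km_fit(rec2)
  s2 <- km2$curve$survival[km2$curve$n_event > 0]
  expect_equal(s2, c(1 / 2, 0), tolerance = 1e-12)

  # all censored: survival stays 1, median not reached
  rec3 <- data.frame(time_days = rep(180, 5), event = rep(FALSE, 5))
  km3 <- km_fit(rec3)
  expect_true(all(km3$curve$survival == 1))
  expect_true(is.na(km3$summary$median))
})

test_that("km_fit with zero censoring equals the empirical survival function", {
  set.seed(5)
  for (i in 1:5) {
    times <- sample(1:30, 20, replace = TRUE)
    rec <- data.frame(time_days = times, event = TRUE)
    km <- km_fit(rec)
    o <- oracle_km(times, rep(TRUE, 20))
    got <- km$curve[km$curve$n_event > 0, ]
    expect_equal(got$time, o$time)
    expect_equal(got$survival, o$survival, tolerance = 1e-12)
    # and the empirical survivor function directly
    expect_equal(got$survival,
                 vapply(o$time, function(t) mean(times > t), numeric(1)),
                 tolerance = 1e-12)
  }
})

test_that("log_rank matches the hypergeometric oracle and guards inputs", {
  rec <- data.frame(time_days = c(1, 2, 10, 11), event = TRUE,
                    grp = c("A", "A", "B", "B"))
  lr <- log_rank(rec, "grp")
  expect_equal(lr$df, 1)
  expect_equal(lr$chisq, oracle_logrank(rec$time_days, rec$event, rec$grp),
               tolerance = 1e-10)

  # identical event-time distributions: statistic near zero
  rec0 <- data.frame(time_days = rep(c(3, 7, 12), 2), event = TRUE,
                     grp = rep(c("A", "B"), each = 3))
  expect_lt(log_rank(rec0, "grp")$chisq, 1e-10)

  rec_bad <- data.frame(time_days = 1:4, event = TRUE,
                        grp = factor(rep("A", 4), levels = c("A", "B")))
  expect_error(log_rank(rec_bad, "grp"), "strata|zero members")
})

test_that("survival_records ties the state machine to strata and the horizon", {
  daily <- data.frame(
    participant_id = rep(c("A", "B"), each = 5),
    day_index = rep(0:4, 2),
    valid_wear_minutes = c(400, 0, 0, 400, 0, rep(0, 5)),
    sleep_wear_minutes = 0L, awake_wear_minutes = 0L,
    completed = c(TRUE, TRUE, FALSE, TRUE, FALSE, rep(FALSE, 5)),
    stress_level = NA_integer_)
  parts <- data.frame(participant_id = c("A", "B"),
                      age_group = c("adult", "child"),
                      tp53_status = "mut", cancer_history = FALSE,
                      stringsAsFactors = FALSE)
  rec <- survival_records(daily, parts, "watch", horizon = 180)
  a <- rec[rec$participant_id == "A", ]
  expect_equal(a$time_days, 4) # exit begins the day after the last active day
  expect_true(a$event)
  b <- rec[rec$participant_id == "B", ]
  expect_equal(b$time_days, 0) # never active
  expect_true(b$event)
  expect_equal(rec$age_group, c("adult", "child"))

  recs <- survival_records(daily, parts, "survey", horizon = 180)
  expect_equal(recs$time_days[recs$participant_id == "A"], 4)
})

test_that("planted retention difference is recovered in a single cohort draw", {
  cfg <- cohort_config(n_children = 200, n_adults = 200,
                       wear_adherence_mean_adult = 0.9,
                       wear_adherence_mean_child = 0.9,
                       wear_adherence_sd_adult = 0,
                       wear_adherence_sd_child = 0,
                       adherence_decay_halflife_days = 1e9,
                       checkin_modulation = 0, scan_participation = 0,
                       seed = 21)
  cohort <- simulate_cohort(cfg)
  rec <- survival_records(cohort$daily, cohort$participants, "watch")
  km <- km_fit(rec, "age_group")
  med <- setNames(km$summary$median, km$summary$stratum)
  # single draw: direction and size of the planted gap (precise recovery is
  # checked over replicates elsewhere)
  expect_gt(med[["adult"]] - med[["child"]], 40)
  expect_lt(abs(med[["adult"]] - 153), 25)
  expect_lt(abs(med[["child"]] - 77), 25)
  expect_lt(log_rank(rec, "age_group")$p_value, 0.05)
})
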