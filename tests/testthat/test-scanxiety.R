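# helpers to build synthetic event datasets directly
make_event <- function(n = 1000, seed = 1, miss = 0, rho = 0) {
  set.seed(seed)
  z <- rnorm(n)
  mix <- function() rho * z + sqrt(1 - rho^2) * rnorm(n)
  ds <- data.frame(
    eda = exp(0.2 * mix()), heart_rate = 75 + 5 * mix(),
    hrv = exp(log(50) + 0.2 * mix()), resp_rate = 16 + 1.5 * mix(),
    temperature = 33 + 0.5 * mix()
  )
  ds$time_to_scan <- seq_len(n)
  attr(ds, "scan_id") <- "test"
  attr(ds, "participant_id") <- "T"
  if (miss > 0) {
    for (ch in c("eda", "heart_rate", "hrv", "resp_rate", "temperature")) {
      ds[[ch]][runif(n) < miss] <- NA
    }
  }
  ds
}

test_that("eligible_events enforces the scan count and wear boundary", {
  parts <- data.frame(participant_id = c("A", "B", "C"))
  scans <- data.frame(participant_id = c("A", "B", "B", "C", "C"),
                      scan_day = c(60, 60, 120, 60, 120))
  wear_of <- function(pid, minutes) {
    data.frame(participant_id = pid, day_index = 0:119,
               valid_wear_minutes = minutes)
  }
  # B: exactly 300 h in every 30-day look-back; C: 299 h before one scan
  daily <- rbind(wear_of("A", 600), wear_of("B", 600),
                 wear_of("C", c(rep(600, 90), rep(598, 30))))
  elig <- eligible_events(parts, scans, daily)
  expect_false("A" %in% elig$participant_id) # only one scan
  expect_true("B" %in% elig$participant_id)  # 600*30/60 = 300 h, inclusive
  expect_false("C" %in% elig$participant_id) # 299 h before the second scan
  expect_equal(nrow(elig[elig$participant_id == "B", ]), 2)
})

test_that("build_event_dataset windows minutes half-open before the scan", {
  ph <- data.frame(participant_id = "A",
                   timestamp_min = c(10 * 1440 - 4320, 10 * 1440 - 1, 10 * 1440),
                   eda = 1, heart_rate = 70, hrv = 50, resp_rate = 15,
                   temperature = 33)
  ds <- build_event_dataset(ph, "A", 10, window_days = 3)
  expect_equal(nrow(ds), 2) # sample at the scan minute is excluded
  expect_equal(ds$time_to_scan, c(4320, 1))

  # full wear, no missingness: 3 x 1440 rows
  full <- data.frame(participant_id = "A",
                     timestamp_min = (7 * 1440):(10 * 1440 - 1),
                     eda = 1, heart_rate = 70, hrv = 50, resp_rate = 15,
                     temperature = 33)
  expect_equal(nrow(build_event_dataset(full, "A", 10, 3)), 4320)
  # nesting: a 1-day window is a subset of the 3-day window
  d1 <- build_event_dataset(full, "A", 10, 1)
  expect_true(all(d1$time_to_scan %in% build_event_dataset(full, "A", 10, 3)$time_to_scan))
  expect_error(build_event_dataset(ph, "A", 3, 1), "empty pre-scan window")
})

test_that("mice_impute is the identity without missingness and never touches observed values", {
  ds <- make_event(500, seed = 2)
  out <- mice_impute(ds)
  expect_identical(out[, physio_cols <- c("eda", "heart_rate", "hrv",
                                          "resp_rate", "temperature")],
                   ds[, physio_cols])
  expect_true(all(out$missingness_fraction == 0))

  dm <- make_event(500, seed = 3, miss = 0.2, rho = 0.9)
  obs_mask <- !is.na(dm[, physio_cols])
  out2 <- mice_impute(dm)
  expect_false(anyNA(out2[, physio_cols]))
  for (ch in physio_cols) {
    expect_identical(out2[[ch]][obs_mask[, ch]], dm[[ch]][obs_mask[, ch]])
  }
  expect_equal(out2$missingness_fraction, rowMeans(!obs_mask))
})

test_that("chained-equation imputation beats mean imputation on correlated channels", {
  truth <- make_event(800, seed = 4, rho = 0.9)
  masked <- truth
  set.seed(5)
  drop_mask <- list()
  chans <- c("eda", "heart_rate", "hrv", "resp_rate", "temperature")
  for (ch in chans) {
    drop_mask[[ch]] <- runif(800) < 0.2
    masked[[ch]][drop_mask[[ch]]] <- NA
  }
  imp <- mice_impute(masked)
  rmse <- function(filled) {
    sqrt(mean(unlist(lapply(chans, function(ch)
      (filled[[ch]][drop_mask[[ch]]] - truth[[ch]][drop_mask[[ch]]])^2))))
  }
  mean_fill <- masked
  for (ch in chans) {
    mean_fill[[ch]][drop_mask[[ch]]] <- mean(masked[[ch]], na.rm = TRUE)
  }
  expect_lt(rmse(imp), rmse(mean_fill))

  # independent channels: nothing to exploit, imputation ~ mean imputation
  truth0 <- make_event(800, seed = 6, rho = 0)
  masked0 <- truth0
  set.seed(7)
  for (ch in chans) {
    drop_mask[[ch]] <- runif(800) < 0.2
    masked0[[ch]][drop_mask[[ch]]] <- NA
  }
  imp0 <- mice_impute(masked0)
  mean0 <- masked0
  for (ch in chans) mean0[[ch]][drop_mask[[ch]]] <- mean(masked0[[ch]], na.rm = TRUE)
  r_imp <- sqrt(mean(unlist(lapply(chans, function(ch)
    (imp0[[ch]][drop_mask[[ch]]] - truth0[[ch]][drop_mask[[ch]]])^2))))
  r_mean <- sqrt(mean(unlist(lapply(chans, function(ch)
    (mean0[[ch]][drop_mask[[ch]]] - truth0[[ch]][drop_mask[[ch]]])^2))))
  expect_lt(abs(r_imp - r_mean) / r_mean, 0.1)

  # guards
  all_missing <- masked
  all_missing$eda <- NA_real_
  expect_error(mice_impute(all_missing), "fully missing")
  sparse <- truth
  sparse$eda[seq_len(700)] <- NA # 12.5% observed
  expect_warning(flagged <- mice_impute(sparse), "flagged")
  expect_true(attr(flagged, "flagged"))
  expect_true(anyNA(flagged$eda))
})

test_that("transform_features z-scores after logging skewed channels", {
  ds <- mice_impute(make_event(2000, seed = 8))
  tf <- transform_features(ds)
  for (f in c("log_eda", "heart_rate", "log_hrv", "resp_rate", "temperature")) {
    expect_equal(mean(tf[[f]]), 0, tolerance = 1e-12)
    expect_equal(sd(tf[[f]]), 1, tolerance = 1e-12)
  }
  # lognormal EDA has positive skew before the log, near none after
  skew <- function(x) mean((x - mean(x))^3) / sd(x)^3
  set.seed(9)
  raw <- exp(rnorm(5000, 0, 0.8))
  expect_gt(skew(raw), 1)
  expect_lt(abs(skew(log(raw))), 0.2)

  bad <- ds; bad$eda[1] <- -1
  expect_error(transform_features(bad), "strictly positive")
  const <- ds; const$temperature <- 33
  expect_warning(tf2 <- transform_features(const), "constant channel dropped")
  expect_false("temperature" %in% attr(tf2, "feature_names"))
})

test_that("fit_gam recovers planted monotone relationships and flat nulls", {
  set.seed(10)
  n <- 3000
  x <- rnorm(n)
  ds <- data.frame(x = x, time_to_scan = 100 + 40 * x + rnorm(n, 0, 10))
  attr(ds, "feature_names") <- "x"
  fit <- fit_gam(ds)
  pdp <- fit$pdp[fit$pdp$feature == "x", ]
  central <- pdp[pdp$value >= quantile(x, 0.1) & pdp$value <= quantile(x, 0.9), ]
  expect_true(all(diff(central$effect) > -1e-8)) # monotone increasing
  expect_gt(cor(central$effect, central$value), 0.99)

  # null response: flat partial dependence, CV error near Var(response)
  ds0 <- data.frame(x = x, time_to_scan = rnorm(n, 0, 1))
  attr(ds0, "feature_names") <- "x"
  fit0 <- fit_gam(ds0)
  expect_lt(max(abs(fit0$pdp$effect)), 0.15 * sd(ds0$time_to_scan))
  set.seed(11)
  cvm <- cross_validate(ds0)
  expect_lt(abs(cvm - var(ds0$time_to_scan)) / var(ds0$time_to_scan), 0.1)

  expect_error(fit_gam(ds[1:100, ]), "too few rows")
  dbad <- ds; dbad$x <- 1
  expect_error(fit_gam(dbad), "rank-deficient")
  expect_error(cross_validate(ds, folds = 1), "folds")
})

test_that("partial dependence scales with affine response rescaling", {
  set.seed(12)
  x <- rnorm(2000)
  ds <- data.frame(x = x, time_to_scan = 50 * sin(x) + rnorm(2000, 0, 5))
  attr(ds, "feature_names") <- "x"
  ds2 <- ds
  ds2$time_to_scan <- 3 * ds$time_to_scan + 7
  f1 <- fit_gam(ds); f2 <- fit_gam(ds2)
  expect_gt(cor(f1$pdp$effect, f2$pdp$effect), 0.999)
  sc <- coef(lm.fit(cbind(1, f1$pdp$effect), f2$pdp$effect))[2]
  expect_equal(unname(sc), 3, tolerance = 0.05)
})

test_that("pdp_similarity separates shared from distinct planted shapes", {
  expect_equal(pdp_similarity(fit <- fit_gam({
    set.seed(13)
    d <- data.frame(x = rnorm(1500), time_to_scan = 0)
    d$time_to_scan <- 30 * d$x^2 + rnorm(1500, 0, 8)
    attr(d, "feature_names") <- "x"
    d
  }), fit, "x"), 1)

  mk <- function(seed, g) {
    set.seed(seed)
    x <- rnorm(1500)
    d <- data.frame(x = x, time_to_scan = g(x) + rnorm(1500, 0, 8))
    attr(d, "feature_names") <- "x"
    d
  }
  same_a <- fit_gam(mk(14, function(x) 30 * x^2))
  same_b <- fit_gam(mk(15, function(x) 30 * x^2))
  diff_c <- fit_gam(mk(16, function(x) -30 * x))
  expect_gt(pdp_similarity(same_a, same_b, "x"), 0.8)
  expect_lt(pdp_similarity(same_a, diff_c, "x"),
            pdp_similarity(same_a, same_b, "x"))
  expect_error(pdp_similarity(same_a, same_b, "zzz"), "not present")
})

test_that("a planted missing-not-at-random mechanism is visible to the model", {
  # missingness inflated toward the scan: the per-minute missingness
  # fraction must carry signal about time_to_scan
  cfg <- cohort_config(n_children = 0, n_adults = 1, dropout_hazard_adult = 0,
                       wear_adherence_mean_adult = 1,
                       wear_adherence_sd_adult = 0, checkin_modulation = 0,
                       adherence_decay_halflife_days = 1e9,
                       scan_participation = 1, missing_rate = 0.1,
                       missing_near_scan_boost = 5, seed = 17)
  p <- generate_cohort(cfg)[1, ]
  w <- simulate_wear(p, cfg)
  sc <- data.frame(participant_id = p$participant_id, scan_day = 90L,
                   modality = "MRI")
  ph <- simulate_physio(p, sc, w, cfg)
  ds <- transform_features(mice_impute(build_event_dataset(ph, p$participant_id, 90)))
  expect_true("missingness_fraction" %in% attr(ds, "feature_names"))
  # more missingness closer to the scan => negative association with time_to_scan
  expect_lt(cor(ds$missingness_fraction, ds$time_to_scan), -0.1)
  fit <- fit_gam(ds)
  pdp <- fit$pdp[fit$pdp$feature == "missingness_fraction", ]
  slope <- coef(lm.fit(cbind(1, pdp$value), pdp$predicted))[2]
  expect_lt(slope, 0)
})
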