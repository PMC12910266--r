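physio_channels <- c("eda", "heart_rate", "hrv", "resp_rate", "temperature")

#' Select participants and scans eligible for scan-proximity modeling
#'
#' Keeps participants with at least `min_scans` scans where every scan is
#' preceded by at least `min_wear_hours` of cumulative valid wear inside the
#' look-back window. The look-back horizon defaults to 30 days; the
#' modeling window itself is much shorter, so eligibility deliberately
#' measures sustained wear rather than window coverage.
#'
#' @param participants Participant table.
#' @param scans Scan table (`participant_id`, `scan_day`).
#' @param daily Daily wear table (`participant_id`, `day_index`,
#'   `valid_wear_minutes`).
#' @param min_scans Minimum number of scans per participant (default 2).
#' @param min_wear_hours Minimum cumulative wear before each scan (default
#'   300 h).
#' @param lookback_days Look-back window for the wear requirement (default
#'   30 days).
#' @return A data.frame of eligible (`participant_id`, `scan_day`,
#'   `scan_id`) rows; zero rows when nobody qualifies.
#' @export
eligible_events <- function(participants, scans, daily, min_scans = 2,
                            min_wear_hours = 300, lookback_days = 30) {
  out <- list()
  for (pid in unique(scans$participant_id)) {
    sc <- scans[scans$participant_id == pid, ]
    if (nrow(sc) < min_scans) next
    d <- daily[daily$participant_id == pid & !is.na(daily$valid_wear_minutes), ]
    ok <- vapply(sc$scan_day, function(day) {
      sel <- d$day_index >= (day - lookback_days) & d$day_index < day
      sum(d$valid_wear_minutes[sel]) / 60 >= min_wear_hours
    }, logical(1))
    if (!all(ok)) next
    out[[length(out) + 1]] <- data.frame(
      participant_id = pid, scan_day = sc$scan_day,
      scan_id = sprintf("%s_scan%02d", pid, seq_len(nrow(sc))),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(participant_id = character(), scan_day = integer(),
                      scan_id = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Build the minute-level dataset for one scan event
#'
#' Restricts minute-level physiology to the half-open pre-scan window
#' `[scan - window_days, scan)` (the scan minute is midnight of `scan_day`
#' unless `scan_minute` is supplied) and attaches the response
#' `time_to_scan` in minutes remaining until the scan.
#'
#' @param physio Minute-level physiology table.
#' @param participant_id,scan_day Identify the event.
#' @param window_days Modeling window before the scan (default 3 days).
#' @param scan_minute Optional scan timestamp in minutes since enrollment;
#'   defaults to `scan_day * 1440`.
#' @param scan_id Optional label carried in the result attributes.
#' @return A data.frame with the five channel columns and `time_to_scan`;
#'   attributes `participant_id` and `scan_id`.
#' @export
build_event_dataset <- function(physio, participant_id, scan_day,
                                window_days = 3, scan_minute = NULL,
                                scan_id = NULL) {
  if (is.null(scan_minute)) scan_minute <- scan_day * 1440
  ph <- physio[physio$participant_id == participant_id, ]
  sel <- ph$timestamp_min >= (scan_minute - window_days * 1440) &
    ph$timestamp_min < scan_minute
  if (!any(sel))
    stop(sprintf("empty pre-scan window for %s at day %s", participant_id,
                 scan_day), call. = FALSE)
  ph <- ph[sel, ]
  out <- ph[, c(physio_channels)]
  out$time_to_scan <- scan_minute - ph$timestamp_min
  attr(out, "participant_id") <- participant_id
  attr(out, "scan_id") <- if (is.null(scan_id))
    sprintf("%s_d%d", participant_id, scan_day) else scan_id
  out
}

#' Chained-equation imputation of physiological channels
#'
#' Single deterministic imputation by chained equations: channels start at
#' their observed means, then each channel in turn is regressed linearly on
#' the other four (rows where it is observed) and its missing entries are
#' replaced by predictions, cycling for `n_iterations` sweeps. Observed
#' values are never altered. The per-minute `missingness_fraction` (number
#' of missing channels / 5) is recorded before imputation. Events where any
#' channel is under 20% observed are flagged and returned unimputed; a
#' fully missing channel is an error.
#'
#' @param dataset Output of [build_event_dataset()].
#' @param n_iterations Sweeps of the chained equations (default 10).
#' @param min_observed Minimum observed fraction per channel (default 0.2).
#' @return The dataset with channels completed and a
#'   `missingness_fraction` column; attribute `flagged` is `TRUE` when
#'   imputation was withheld.
#' @export
mice_impute <- function(dataset, n_iterations = 10, min_observed = 0.2) {
  X <- as.matrix(dataset[, physio_channels])
  n <- nrow(X)
  miss <- is.na(X)
  dataset$missingness_fraction <- rowMeans(miss)
  obs_frac <- 1 - colMeans(miss)
  if (any(obs_frac == 0))
    stop("fully missing channel(s): ",
         paste(physio_channels[obs_frac == 0], collapse = ", "), call. = FALSE)
  attr(dataset, "flagged") <- any(obs_frac < min_observed)
  if (attr(dataset, "flagged")) {
    warning("channel(s) under ", 100 * min_observed,
            "% observed; event flagged, not imputed")
    return(dataset)
  }
  if (!any(miss)) return(dataset)
  # mean initialization
  for (j in seq_len(ncol(X))) X[miss[, j], j] <- mean(X[!miss[, j], j])
  for (it in seq_len(n_iterations)) {
    for (j in seq_len(ncol(X))) {
      mj <- miss[, j]
      if (!any(mj)) next
      design <- cbind(1, X[, -j, drop = FALSE])
      fit <- lm.fit(design[!mj, , drop = FALSE], X[!mj, j])
      X[mj, j] <- design[mj, , drop = FALSE] %*% fit$coefficients
    }
  }
  dataset[, physio_channels] <- X
  dataset
}

#' Log-transform and z-score event features
#'
#' Natural log on EDA and HRV (to reduce their positive skew), then
#' per-event z-scoring of all five channels to zero mean and unit variance.
#' The `missingness_fraction` column is left on its natural `[0, 1]` scale.
#' A constant channel has no z-score and is dropped with a warning.
#'
#' @param dataset Output of [mice_impute()] (channels complete).
#' @return The dataset with columns `log_eda`, `heart_rate`, `log_hrv`,
#'   `resp_rate`, `temperature` (z-scored), `missingness_fraction` and
#'   `time_to_scan`; attribute `feature_names` lists the retained features.
#' @export
transform_features <- function(dataset) {
  for (ch in c("eda", "hrv")) {
    v <- dataset[[ch]]
    if (any(v <= 0, na.rm = TRUE))
      stop(ch, " must be strictly positive before log transform", call. = FALSE)
  }
  out <- data.frame(
    log_eda = log(dataset$eda),
    heart_rate = dataset$heart_rate,
    log_hrv = log(dataset$hrv),
    resp_rate = dataset$resp_rate,
    temperature = dataset$temperature
  )
  keep <- character()
  for (nm in names(out)) {
    s <- sd(out[[nm]])
    if (is.na(s) || s == 0) {
      warning("constant channel dropped: ", nm)
      out[[nm]] <- NULL
    } else {
      out[[nm]] <- (out[[nm]] - mean(out[[nm]])) / s
      keep <- c(keep, nm)
    }
  }
  if (!is.null(dataset$missingness_fraction)) {
    out$missingness_fraction <- dataset$missingness_fraction
    if (sd(out$missingness_fraction) > 0) keep <- c(keep, "missingness_fraction")
  }
  out$time_to_scan <- dataset$time_to_scan
  attr(out, "participant_id") <- attr(dataset, "participant_id")
  attr(out, "scan_id") <- attr(dataset, "scan_id")
  attr(out, "feature_names") <- keep
  out
}

gam_formula <- function(dataset, features, k_basis = 20) {
  terms <- vapply(features, function(f) {
    nu <- length(unique(dataset[[f]]))
    if (nu < 4) f # too few distinct values for a spline; linear term
    else sprintf("s(%s, bs = \"cr\", k = %d)", f, min(k_basis, nu - 1))
  }, character(1))
  stats::as.formula(paste("time_to_scan ~", paste(terms, collapse = " + ")))
}

#' Fit the per-event additive model of scan proximity
#'
#' Additive model with the minutes-to-scan response and one cubic
#' regression spline per feature (the five z-scored physiological channels
#' plus the missingness fraction), no interactions; smoothing parameters
#' selected by REML. Each smooth uses up to `k_basis` basis functions,
#' reduced automatically for low-cardinality features (the missingness
#' fraction takes at most six values). Partial dependence is evaluated on a
#' 100-point grid spanning each feature's observed range.
#'
#' @param dataset Output of [transform_features()].
#' @param k_basis Basis dimension per smooth (default 20).
#' @param min_rows Minimum rows required (default 500).
#' @param grid_points Partial-dependence grid size (default 100).
#' @return An object of class `gam_fit`: list with `model` (the
#'   [mgcv::gam] fit), `pdp` (long data.frame `feature`, `value`, `effect`,
#'   `predicted`), `features`, `scan_id`, `participant_id`, `smoothing`
#'   (REML-selected smoothing parameters).
#' @export
fit_gam <- function(dataset, k_basis = 20, min_rows = 500, grid_points = 100) {
  features <- attr(dataset, "feature_names")
  if (is.null(features))
    features <- setdiff(names(dataset), "time_to_scan")
  if (nrow(dataset) < min_rows)
    stop(sprintf("too few rows for a stable fit (%d < %d)", nrow(dataset),
                 min_rows), call. = FALSE)
  for (f in features) {
    if (sd(dataset[[f]]) == 0)
      stop("rank-deficient design: feature '", f, "' is constant", call. = FALSE)
  }
  form <- gam_formula(dataset, features, k_basis)
  model <- gam(form, data = dataset, method = "REML")
  means <- vapply(dataset[features], mean, numeric(1))
  pdp <- do.call(rbind, lapply(features, function(f) {
    grid <- seq(min(dataset[[f]]), max(dataset[[f]]), length.out = grid_points)
    nd <- as.data.frame(as.list(means))[rep(1, grid_points), , drop = FALSE]
    nd[[f]] <- grid
    tm <- predict(model, newdata = nd, type = "terms")
    col <- grep(paste0("(^|\\()", f, "(,|\\))"), colnames(tm))
    if (length(col) == 0) col <- which(colnames(tm) == f)
    eff <- as.numeric(tm[, col[1]])
    data.frame(feature = f, value = grid, effect = eff,
               predicted = eff + attr(tm, "constant"), stringsAsFactors = FALSE)
  }))
  structure(list(model = model, pdp = pdp, features = features,
                 scan_id = attr(dataset, "scan_id"),
                 participant_id = attr(dataset, "participant_id"),
                 smoothing = model$sp, n = nrow(dataset)),
            class = "gam_fit")
}

#' @export
print.gam_fit <- function(x, ...) {
  cat(sprintf("scan-proximity GAM for event %s (%d minutes, %d features)\n",
              x$scan_id %||% "<unnamed>", x$n, length(x$features)))
  cat("  features:", paste(x$features, collapse = ", "), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cross-validated mean squared error of the event GAM
#'
#' Row-wise K-fold cross-validation (shuffled under the current RNG state):
#' the model of [fit_gam()] is refit on each training split and scored on
#' the held-out rows; the mean of the fold MSEs is returned.
#'
#' @param dataset Output of [transform_features()].
#' @param folds Number of folds (default 5).
#' @param k_basis Basis dimension per smooth.
#' @return Mean held-out MSE across folds.
#' @export
cross_validate <- function(dataset, folds = 5, k_basis = 20) {
  n <- nrow(dataset)
  if (folds < 2) stop("folds must be >= 2", call. = FALSE)
  if (n < folds * 50) stop("too few rows for ", folds, "-fold CV", call. = FALSE)
  features <- attr(dataset, "feature_names") %||%
    setdiff(names(dataset), "time_to_scan")
  form <- gam_formula(dataset, features, k_basis)
  fold_id <- sample(rep(seq_len(folds), length.out = n))
  mse <- vapply(seq_len(folds), function(f) {
    train <- dataset[fold_id != f, , drop = FALSE]
    test <- dataset[fold_id == f, , drop = FALSE]
    m <- gam(form, data = train, method = "REML")
    pred <- predict(m, newdata = test)
    mean((test$time_to_scan - pred)^2)
  }, numeric(1))
  mean(mse)
}

#' Similarity of partial dependence across two event fits
#'
#' Pearson correlation of two partial-dependence curves for one feature,
#' re-evaluated by linear interpolation on a shared grid spanning the
#' intersection of the two observed feature ranges. Quantifies whether the
#' physiological dependence pattern is conserved (e.g. across two scans of
#' the same person).
#'
#' @param fit_a,fit_b `gam_fit` objects.
#' @param feature Feature name present in both fits.
#' @param grid_points Shared grid size (default 100).
#' @return Pearson r, or `NA` (with a warning) for disjoint ranges.
#' @export
pdp_similarity <- function(fit_a, fit_b, feature, grid_points = 100) {
  pa <- fit_a$pdp[fit_a$pdp$feature == feature, ]
  pb <- fit_b$pdp[fit_b$pdp$feature == feature, ]
  if (nrow(pa) == 0 || nrow(pb) == 0)
    stop("feature '", feature, "' not present in both fits", call. = FALSE)
  lo <- max(min(pa$value), min(pb$value))
  hi <- min(max(pa$value), max(pb$value))
  if (lo >= hi) {
    warning("disjoint feature ranges; similarity undefined")
    return(NA_real_)
  }
  grid <- seq(lo, hi, length.out = grid_points)
  ya <- stats::approx(pa$value, pa$effect, xout = grid)$y
  yb <- stats::approx(pb$value, pb$effect, xout = grid)$y
  if (sd(ya) == 0 || sd(yb) == 0) {
    warning("flat partial dependence; similarity undefined")
    return(NA_real_)
  }
  cor(ya, yb)
}

#' End-to-end scan-proximity analysis for a cohort
#'
#' Runs eligibility, per-event dataset construction, imputation, transforms,
#' GAM fitting and cross-validation, then the within-person
#' partial-dependence similarity for every participant with multiple fitted
#' events.
#'
#' @param participants,scans,daily,physio Cohort tables (simulated or
#'   user-supplied with the same schemas).
#' @param window_days Modeling window before each scan (default 3).
#' @param folds CV folds (default 5).
#' @param min_scans,min_wear_hours,lookback_days Eligibility settings.
#' @param k_basis Basis dimension per smooth.
#' @param min_rows Minimum rows per event.
#' @return A list with `eligible`, `fits` (named by scan id), `cv` (scan id,
#'   cv_mse, n rows) and `similarity` (participant, feature, scan pair,
#'   Pearson r). Events that fail (empty window, too few rows, flagged
#'   imputation) are skipped with a message and listed in `skipped`.
#' @export
scanxiety_analysis <- function(participants, scans, daily, physio,
                               window_days = 3, folds = 5, min_scans = 2,
                               min_wear_hours = 300, lookback_days = 30,
                               k_basis = 20, min_rows = 500) {
  elig <- eligible_events(participants, scans, daily, min_scans,
                          min_wear_hours, lookback_days)
  fits <- list(); cv_rows <- list(); skipped <- list()
  for (i in seq_len(nrow(elig))) {
    sid <- elig$scan_id[i]
    res <- tryCatch({
      ds <- build_event_dataset(physio, elig$participant_id[i],
                                elig$scan_day[i], window_days, scan_id = sid)
      ds <- mice_impute(ds)
      if (isTRUE(attr(ds, "flagged"))) stop("event flagged by imputation guard")
      ds <- transform_features(ds)
      fit <- fit_gam(ds, k_basis = k_basis, min_rows = min_rows)
      cvm <- cross_validate(ds, folds = folds, k_basis = k_basis)
      list(fit = fit, cv = cvm, n = nrow(ds))
    }, error = function(e) e, warning = function(w) {
      # constant-channel warnings are tolerated; rerun quietly
      tryCatch({
        ds <- build_event_dataset(physio, elig$participant_id[i],
                                  elig$scan_day[i], window_days, scan_id = sid)
        ds <- suppressWarnings(mice_impute(ds))
        if (isTRUE(attr(ds, "flagged"))) stop("event flagged by imputation guard")
        ds <- suppressWarnings(transform_features(ds))
        fit <- fit_gam(ds, k_basis = k_basis, min_rows = min_rows)
        cvm <- cross_validate(ds, folds = folds, k_basis = k_basis)
        list(fit = fit, cv = cvm, n = nrow(ds))
      }, error = function(e) e)
    })
    if (inherits(res, "error")) {
      message("skipping event ", sid, ": ", conditionMessage(res))
      skipped[[length(skipped) + 1]] <- data.frame(
        scan_id = sid, reason = conditionMessage(res), stringsAsFactors = FALSE)
      next
    }
    fits[[sid]] <- res$fit
    cv_rows[[length(cv_rows) + 1]] <- data.frame(
      scan_id = sid, participant_id = elig$participant_id[i],
      cv_mse = res$cv, n = res$n, stringsAsFactors = FALSE)
  }
  sim <- list()
  by_pid <- split(names(fits), vapply(fits, function(f) f$participant_id,
                                      character(1)))
  for (pid in names(by_pid)) {
    ids <- by_pid[[pid]]
    if (length(ids) < 2) next
    pairs <- utils::combn(ids, 2, simplify = FALSE)
    for (pr in pairs) {
      common <- intersect(fits[[pr[1]]]$features, fits[[pr[2]]]$features)
      for (f in common) {
        r <- tryCatch(suppressWarnings(
          pdp_similarity(fits[[pr[1]]], fits[[pr[2]]], f)),
          error = function(e) NA_real_)
        sim[[length(sim) + 1]] <- data.frame(
          participant_id = pid, scan_a = pr[1], scan_b = pr[2], feature = f,
          pearson_r = r, stringsAsFactors = FALSE)
      }
    }
  }
  list(
    eligible = elig,
    fits = fits,
    cv = if (length(cv_rows)) do.call(rbind, cv_rows) else NULL,
    similarity = if (length(sim)) do.call(rbind, sim) else NULL,
    skipped = if (length(skipped)) do.call(rbind, skipped) else NULL
  )
}
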