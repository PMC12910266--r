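#' Classify a wear day as active
#'
#' A day is active when valid wear minutes reach the threshold (default 6 h,
#' inclusive). A 1-hour variant of the threshold supports the secondary wear
#' definition reported alongside the primary one.
#'
#' @param valid_wear_minutes Integer vector of per-day valid wear minutes
#'   (post artifact exclusion).
#' @param threshold_hours Activity threshold in hours (default 6).
#' @return Logical vector.
#' @examples
#' daily_watch_active(c(360, 359, 90), threshold_hours = 6)
#' @export
daily_watch_active <- function(valid_wear_minutes, threshold_hours = 6) {
  if (any(valid_wear_minutes < 0, na.rm = TRUE))
    stop("valid_wear_minutes must be non-negative", call. = FALSE)
  !is.na(valid_wear_minutes) & valid_wear_minutes >= threshold_hours * 60
}

#' Engagement rate over the observed span
#'
#' Fraction of observed days that are active. The observed span runs from
#' day 0 through the last day with any record (`denominator = "observed"`,
#' the default) or through the full horizon (`denominator = "horizon"`);
#' days inside the span with no record count as nonactive.
#'
#' @param active Logical per-day activity, `NA` for days without a record.
#' @param denominator `"observed"` or `"horizon"`.
#' @param horizon_days Follow-up cap in days (default 180).
#' @return A fraction in `[0, 1]`.
#' @export
engagement_rate <- function(active, denominator = c("observed", "horizon"),
                            horizon_days = 180) {
  denominator <- match.arg(denominator)
  if (length(active) == 0) stop("empty engagement series", call. = FALSE)
  active <- utils::head(active, horizon_days)
  n_active <- sum(active, na.rm = TRUE)
  n_days <- if (denominator == "observed") length(active) else horizon_days
  n_active / n_days
}

#' Centered rolling mean with truncated edge windows
#'
#' Value at day `t` is the mean of available observations in
#' `[t - (window-1)/2, t + (window-1)/2]`; windows are truncated at the
#' series edges (preserving series length for downstream spectral analysis)
#' and missing values are excluded from the window mean rather than imputed
#' as zero. A window with no observations yields `NA`.
#'
#' @param x Numeric (or logical) series; `NA` marks missing days.
#' @param window Odd window length >= 1 (default 7 days).
#' @return Numeric series of the same length as `x`.
#' @examples
#' rolling_smooth(c(0, 0, 0, 1, 0, 0, 0))
#' @export
rolling_smooth <- function(x, window = 7) {
  if (window < 1 || window %% 2 == 0)
    stop("window must be odd and >= 1", call. = FALSE)
  x <- as.numeric(x)
  n <- length(x)
  h <- (window - 1) / 2
  obs <- !is.na(x)
  x0 <- ifelse(obs, x, 0)
  cs <- cumsum(c(0, x0))
  cn <- cumsum(c(0, as.numeric(obs)))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  s <- cs[hi + 1] - cs[lo]
  k <- cn[hi + 1] - cn[lo]
  out <- ifelse(k > 0, s / k, NA_real_)
  out
}

#' Pearson coupling between smoothed watch and survey series
#'
#' Pearson correlation of two smoothed engagement series on their
#' day-aligned overlap. A constant series makes the correlation undefined;
#' `NA` is returned with a warning rather than 0.
#'
#' @param watch_smoothed,survey_smoothed Numeric series aligned on day
#'   index (equal length).
#' @return Pearson r, or `NA` when undefined.
#' @export
coupling <- function(watch_smoothed, survey_smoothed) {
  if (length(watch_smoothed) != length(survey_smoothed))
    stop("series must be day-aligned (equal length)", call. = FALSE)
  ok <- !is.na(watch_smoothed) & !is.na(survey_smoothed)
  if (sum(ok) < 3) {
    warning("fewer than 3 overlapping days; coupling undefined")
    return(NA_real_)
  }
  a <- watch_smoothed[ok]; b <- survey_smoothed[ok]
  if (sd(a) == 0 || sd(b) == 0) {
    warning("constant series; coupling undefined")
    return(NA_real_)
  }
  cor(a, b)
}

#' Welch two-sample t test
#'
#' Two-sided two-sample t test with the Welch correction (Satterthwaite
#' degrees of freedom), robust to unequal variances and unbalanced groups.
#' With zero variance in both groups and equal means, `t = 0`, `p = 1`.
#'
#' @param a,b Numeric vectors, each with at least 2 finite values.
#' @return An object of class `welch_result` with `t_statistic`, `df`,
#'   `p_value`, `group_means`, `group_sds`, `group_ns`.
#' @examples
#' welch_t(c(1, 2, 3), c(4, 5, 6))
#' @export
welch_t <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 finite values", call. = FALSE)
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) {
      res <- list(t_statistic = 0, df = length(a) + length(b) - 2, p_value = 1)
    } else {
      res <- list(t_statistic = sign(mean(a) - mean(b)) * Inf,
                  df = length(a) + length(b) - 2, p_value = 0)
    }
  } else {
    tt <- stats::t.test(a, b) # Welch is the default
    res <- list(t_statistic = unname(tt$statistic), df = unname(tt$parameter),
                p_value = tt$p.value)
  }
  structure(c(res, list(group_means = c(mean(a), mean(b)),
                        group_sds = c(sd(a), sd(b)),
                        group_ns = c(length(a), length(b)))),
            class = "welch_result")
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf("Welch two-sample t test: t(%.1f) = %.3f, p = %.3g\n",
              x$df, x$t_statistic, x$p_value))
  cat(sprintf("  group means %.3f vs %.3f (SD %.3f vs %.3f; n = %d vs %d)\n",
              x$group_means[1], x$group_means[2], x$group_sds[1],
              x$group_sds[2], x$group_ns[1], x$group_ns[2]))
  invisible(x)
}

# per-participant day-aligned activity vector over day 0..last observed day,
# with NA for days that have no record at all
activity_vector <- function(day_index, active, span = NULL) {
  last <- if (is.null(span)) max(day_index) else span - 1L
  out <- rep(NA, last + 1L)
  keep <- day_index <= last
  out[day_index[keep] + 1L] <- active[keep]
  out
}

#' Per-participant engagement series for both modalities
#'
#' Builds day-aligned activity and smoothed series per participant and
#' modality from a merged daily table (wear + survey records on
#' `participant_id`, `day_index`).
#'
#' @param daily Daily table with columns `participant_id`, `day_index`,
#'   `valid_wear_minutes`, `completed`.
#' @param threshold_hours Watch activity threshold in hours.
#' @param window Smoothing window (odd, days).
#' @return A list keyed by participant id; each element holds `watch` and
#'   `survey` lists with `active` (logical, `NA` = no record) and `smoothed`
#'   vectors over day 0..last observed day.
#' @export
engagement_series <- function(daily, threshold_hours = 6, window = 7) {
  out <- list()
  for (pid in unique(daily$participant_id)) {
    d <- daily[daily$participant_id == pid, ]
    watch_active <- activity_vector(d$day_index,
                                    daily_watch_active(ifelse(is.na(d$valid_wear_minutes), 0,
                                                              d$valid_wear_minutes),
                                                       threshold_hours))
    survey_active <- activity_vector(d$day_index,
                                     !is.na(d$completed) & d$completed)
    out[[pid]] <- list(
      watch = list(active = watch_active,
                   smoothed = rolling_smooth(watch_active, window)),
      survey = list(active = survey_active,
                    smoothed = rolling_smooth(survey_active, window))
    )
  }
  out
}

#' Per-participant engagement summary
#'
#' One row per participant and modality with the engagement rate (days with
#' no record counted as nonactive) and the watch-survey coupling correlation.
#'
#' @inheritParams engagement_series
#' @param denominator Passed to [engagement_rate()].
#' @param horizon_days Follow-up cap in days.
#' @return A data.frame `participant_id`, `modality`, `rate`, `coupling_r`.
#' @export
engagement_summary <- function(daily, threshold_hours = 6, window = 7,
                               denominator = "observed", horizon_days = 180) {
  series <- engagement_series(daily, threshold_hours, window)
  rows <- lapply(names(series), function(pid) {
    s <- series[[pid]]
    r <- tryCatch(suppressWarnings(coupling(s$watch$smoothed, s$survey$smoothed)),
                  error = function(e) NA_real_)
    # no-record days are nonactive for rates (missing only for smoothing)
    rate_of <- function(a) engagement_rate(ifelse(is.na(a), FALSE, a),
                                           denominator, horizon_days)
    data.frame(participant_id = pid,
               modality = c("watch", "survey"),
               rate = c(rate_of(s$watch$active), rate_of(s$survey$active)),
               coupling_r = r,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Stratified wear-time summary table
#'
#' Per-stratum mean (SD) of percent days worn, total wear hours per worn
#' day, and the sleep/awake split, computed only over days meeting the
#' activity threshold. An empty stratum yields a row of `NA`s rather than
#' being dropped.
#'
#' @param daily Daily table (see [engagement_series()]).
#' @param participants Participant table with `participant_id` and the
#'   stratum column.
#' @param stratum Name of the stratum column (default `"age_group"`).
#' @param threshold_hours Activity threshold in hours.
#' @param denominator,horizon_days Passed to [engagement_rate()].
#' @return A data.frame, one row per stratum level, with `n` and
#'   mean/SD columns for each wear metric.
#' @export
wear_time_summary <- function(daily, participants, stratum = "age_group",
                              threshold_hours = 6, denominator = "observed",
                              horizon_days = 180) {
  levels_ <- unique(participants[[stratum]])
  per_participant <- lapply(participants$participant_id, function(pid) {
    d <- daily[daily$participant_id == pid & !is.na(daily$valid_wear_minutes), ]
    if (nrow(d) == 0) {
      return(data.frame(participant_id = pid, pct_days_worn = NA_real_,
                        wear_hours = NA_real_, sleep_hours = NA_real_,
                        awake_hours = NA_real_, stringsAsFactors = FALSE))
    }
    act <- daily_watch_active(d$valid_wear_minutes, threshold_hours)
    rate <- engagement_rate(activity_vector(d$day_index, act),
                            denominator, horizon_days)
    rate <- ifelse(is.na(rate), 0, rate)
    worn <- d[act, ]
    data.frame(participant_id = pid,
               pct_days_worn = 100 * rate,
               wear_hours = if (nrow(worn)) mean(worn$valid_wear_minutes) / 60 else NA_real_,
               sleep_hours = if (nrow(worn)) mean(worn$sleep_wear_minutes) / 60 else NA_real_,
               awake_hours = if (nrow(worn)) mean(worn$awake_wear_minutes) / 60 else NA_real_,
               stringsAsFactors = FALSE)
  })
  pp <- do.call(rbind, per_participant)
  pp <- merge(pp, participants[, c("participant_id", stratum)],
              by = "participant_id")
  rows <- lapply(levels_, function(lv) {
    g <- pp[pp[[stratum]] == lv, ]
    msd <- function(v) {
      v <- v[!is.na(v)]
      if (length(v) == 0) c(NA_real_, NA_real_) else c(mean(v), sd(v))
    }
    stats_ <- c(msd(g$pct_days_worn), msd(g$wear_hours), msd(g$sleep_hours),
                msd(g$awake_hours))
    data.frame(stratum = lv, n = nrow(g),
               pct_days_worn_mean = stats_[1], pct_days_worn_sd = stats_[2],
               wear_hours_mean = stats_[3], wear_hours_sd = stats_[4],
               sleep_hours_mean = stats_[5], sleep_hours_sd = stats_[6],
               awake_hours_mean = stats_[7], awake_hours_sd = stats_[8],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[1] <- stratum
  out
}

#' Welch group comparisons of engagement rates
#'
#' Compares per-participant engagement rates between the two levels of each
#' requested stratum, per modality, with [welch_t()]. No multiplicity
#' correction is applied.
#'
#' @param summary_df Output of [engagement_summary()].
#' @param participants Participant table.
#' @param strata Character vector of stratum column names.
#' @return A data.frame `stratum`, `modality`, group labels, `t`, `df`, `p`.
#' @export
engagement_group_tests <- function(summary_df, participants,
                                   strata = c("age_group", "tp53_status",
                                              "cancer_history")) {
  m <- merge(summary_df, participants, by = "participant_id")
  rows <- list()
  for (st in strata) {
    lvls <- sort(unique(as.character(m[[st]])), decreasing = TRUE)
    if (length(lvls) != 2) next
    for (mod in c("watch", "survey")) {
      a <- m$rate[m$modality == mod & as.character(m[[st]]) == lvls[1]]
      b <- m$rate[m$modality == mod & as.character(m[[st]]) == lvls[2]]
      if (length(a) < 2 || length(b) < 2) {
        rows[[length(rows) + 1]] <- data.frame(
          stratum = st, modality = mod, group_a = lvls[1], group_b = lvls[2],
          mean_a = mean(a), mean_b = mean(b), t = NA_real_, df = NA_real_,
          p = NA_real_, stringsAsFactors = FALSE)
        next
      }
      w <- welch_t(a, b)
      rows[[length(rows) + 1]] <- data.frame(
        stratum = st, modality = mod, group_a = lvls[1], group_b = lvls[2],
        mean_a = w$group_means[1], mean_b = w$group_means[2],
        t = w$t_statistic, df = w$df, p = w$p_value, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
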