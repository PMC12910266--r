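#' Classify days into active / inactive / exit states
#'
#' Implements the two-pass day-state rule used to define disengagement:
#' every nonactive day is initially an "exit" day; nonactive days followed
#' (at any later day) by an active day are reclassified as "inactive"
#' (temporary disengagement), so exit states survive only as a single
#' terminal contiguous run. Days with no record (`NA`) are treated as
#' nonactive: a participant who stops syncing is disengaged, not censored.
#'
#' @param active Logical per-day activity from day 0; `NA` = no record.
#' @return Character vector of states (`"active"`, `"inactive"`, `"exit"`),
#'   class `day_states`.
#' @examples
#' classify_states(c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE))
#' @export
classify_states <- function(active) {
  if (length(active) == 0) stop("empty day series", call. = FALSE)
  active <- !is.na(active) & active
  n <- length(active)
  states <- rep("exit", n)
  states[active] <- "active"
  if (any(active)) {
    last_active <- max(which(active))
    states[!active & seq_len(n) < last_active] <- "inactive"
  }
  structure(states, class = "day_states")
}

#' @export
print.day_states <- function(x, ...) {
  tab <- table(factor(unclass(x), levels = c("active", "inactive", "exit")))
  cat(sprintf("day states over %d days: %d active, %d inactive, %d exit\n",
              length(x), tab["active"], tab["inactive"], tab["exit"]))
  invisible(x)
}

#' First sustained exit as a survival record
#'
#' The disengagement event is the onset of the terminal exit run: the event
#' time is the day index (0-based) of its first day. The event counts only
#' if it falls within the horizon; otherwise — and when the series ends on
#' an active day — the participant is censored at
#' `min(number of observed days, horizon)`.
#'
#' @param states Output of [classify_states()].
#' @param horizon Follow-up horizon in days (default 180).
#' @return A list with `time_days` and `event` (logical).
#' @examples
#' first_sustained_exit(classify_states(c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE)))
#' @export
first_sustained_exit <- function(states, horizon = 180) {
  s <- unclass(states)
  n <- length(s)
  censor_time <- min(n, horizon)
  if (s[n] != "exit") {
    return(list(time_days = censor_time, event = FALSE))
  }
  exit_start <- max(which(s != "exit"), 0L) # 0 when never active
  t <- exit_start # 0-based index of first exit day
  if (t <= horizon) list(time_days = t, event = TRUE)
  else list(time_days = censor_time, event = FALSE)
}

#' Build survival records for a cohort and modality
#'
#' For each participant, extends the day-aligned activity series to the
#' horizon (days without a record are nonactive), classifies day states and
#' derives the first-sustained-exit event.
#'
#' @param daily Daily table (see [engagement_series()]).
#' @param participants Participant table carrying the strata columns
#'   (`age_group`, `tp53_status`, `cancer_history`).
#' @param modality `"watch"` or `"survey"`.
#' @param threshold_hours Watch activity threshold (ignored for surveys).
#' @param horizon Follow-up horizon in days.
#' @return A data.frame `participant_id`, `modality`, `time_days`, `event`,
#'   plus the strata columns.
#' @export
survival_records <- function(daily, participants, modality = c("watch", "survey"),
                             threshold_hours = 6, horizon = 180) {
  modality <- match.arg(modality)
  rows <- lapply(seq_len(nrow(participants)), function(i) {
    pid <- participants$participant_id[i]
    d <- daily[daily$participant_id == pid, ]
    act <- rep(FALSE, horizon)
    if (nrow(d) > 0) {
      a <- if (modality == "watch") {
        daily_watch_active(ifelse(is.na(d$valid_wear_minutes), 0,
                                  d$valid_wear_minutes), threshold_hours)
      } else {
        !is.na(d$completed) & d$completed
      }
      keep <- d$day_index < horizon
      act[d$day_index[keep] + 1L] <- a[keep]
    }
    ev <- first_sustained_exit(classify_states(act), horizon)
    data.frame(participant_id = pid, modality = modality,
               time_days = ev$time_days, event = ev$event,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  strata_cols <- intersect(c("age_group", "tp53_status", "cancer_history"),
                           names(participants))
  merge(out, participants[, c("participant_id", strata_cols)],
        by = "participant_id", sort = FALSE)
}

#' Kaplan-Meier fit with median and IQR summaries
#'
#' Product-limit estimate of the retention function, optionally stratified.
#' The median is the smallest time with survival at or below one half; the
#' IQR bounds come from survival at or below 0.75 and 0.25. 95% CIs for the
#' quantiles invert the log-log confidence band (the Brookmeyer-Crowley
#' construction). When all records are censored the median is not reached
#' and reported as `NA`.
#'
#' @param records Survival record data.frame (`time_days`, `event`, strata).
#' @param stratum Optional stratum column name; `NULL` fits the pooled curve.
#' @return An object of class `km_curve`: list with `curve` (time, survival,
#'   at-risk table), `summary` (median/IQR with CIs per stratum) and the
#'   underlying [survival::survfit] object.
#' @examples
#' rec <- data.frame(time_days = c(1, 2, 3), event = c(TRUE, TRUE, TRUE))
#' km_fit(rec)$summary
#' @export
km_fit <- function(records, stratum = NULL) {
  if (nrow(records) < 1) stop("need at least one survival record", call. = FALSE)
  if (is.null(stratum)) {
    fit <- survfit(Surv(time_days, event) ~ 1, data = records,
                   conf.type = "log-log")
    groups <- "all"
  } else {
    records$.group <- as.factor(records[[stratum]])
    fit <- survfit(Surv(time_days, event) ~ .group, data = records,
                   conf.type = "log-log")
    groups <- levels(records$.group)
  }
  sf <- summary(fit, censored = TRUE)
  strata_lab <- if (is.null(stratum)) rep("all", length(sf$time)) else
    sub("^\\.group=", "", as.character(sf$strata))
  curve <- data.frame(stratum = strata_lab, time = sf$time,
                      survival = sf$surv, at_risk = sf$n.risk,
                      n_event = sf$n.event, stringsAsFactors = FALSE)
  q <- quantile(fit, probs = c(0.25, 0.5, 0.75))
  qm <- function(x) {
    if (is.null(dim(x))) x <- matrix(x, nrow = 1, dimnames = list(groups, names(x)))
    x
  }
  qs <- qm(q$quantile); ql <- qm(q$lower); qu <- qm(q$upper)
  summary_df <- data.frame(
    stratum = groups,
    n = if (is.null(stratum)) nrow(records) else
      as.vector(table(records$.group)[groups]),
    median = qs[, 2], iqr_lower = qs[, 1], iqr_upper = qs[, 3],
    median_ci_lower = ql[, 2], median_ci_upper = qu[, 2],
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(curve = curve, summary = summary_df, fit = fit),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier retention fit\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Log-rank comparison of retention across strata
#'
#' Standard (k-sample) log-rank test of the first-sustained-exit survival
#' distributions between stratum levels.
#'
#' @param records Survival record data.frame.
#' @param stratum Stratum column name.
#' @return A list `chisq`, `df`, `p_value`, `n_per_group`.
#' @export
log_rank <- function(records, stratum) {
  g <- as.factor(records[[stratum]])
  if (nlevels(g) < 2) stop("need at least 2 strata", call. = FALSE)
  if (any(table(g) == 0)) stop("a stratum level has zero members", call. = FALSE)
  if (sum(records$event) < 1) stop("need at least one event", call. = FALSE)
  records$.group <- g
  sd_ <- survdiff(Surv(time_days, event) ~ .group, data = records)
  df <- length(sd_$n) - 1
  list(chisq = unname(sd_$chisq), df = df,
       p_value = stats::pchisq(sd_$chisq, df, lower.tail = FALSE),
       n_per_group = as.vector(sd_$n))
}
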