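#' Score a questionnaire instrument
#'
#' Validates item counts/ranges and returns the instrument total. PSS-4
#' items 2 and 3 are reverse-scored (`x -> max - x`) before summation;
#' PHQ-9 and GAD-7 items are 0-3, PSS-4 items 0-4, PROMIS
#' sleep-related-impairment items 1-5 (raw-sum scoring).
#'
#' @param instrument One of `"PHQ9"`, `"GAD7"`, `"PSS4"`, `"PROMIS_SRI"`.
#' @param items Integer vector of raw item responses, in instrument order.
#' @return The integer total score.
#' @examples
#' score_instrument("PSS4", c(4, 0, 0, 4)) # 4 + (4-0) + (4-0) + 4 = 16
#' @export
score_instrument <- function(instrument, items) {
  specs <- instrument_spec()
  if (!instrument %in% names(specs))
    stop("unknown instrument: ", instrument, call. = FALSE)
  spec <- specs[[instrument]]
  if (length(items) != spec$n_items)
    stop(sprintf("%s needs %d items, got %d", instrument, spec$n_items,
                 length(items)), call. = FALSE)
  bad <- which(is.na(items) | items < spec$min | items > spec$max)
  if (length(bad) > 0)
    stop(sprintf("%s item %d out of range [%d, %d]", instrument, bad[1],
                 spec$min, spec$max), call. = FALSE)
  scored <- items
  if (length(spec$reverse) > 0)
    scored[spec$reverse] <- (spec$max + spec$min) - items[spec$reverse]
  as.integer(sum(scored))
}

#' Check a PHQ-9 response for a self-harm alert
#'
#' PHQ-9 item 9 asks about self-harm and suicide-related thoughts; any
#' positive response (1-3) raises an alert. Alerting is a non-blocking side
#' channel: the function only reports, it never modifies the response.
#'
#' @param items PHQ-9 item vector (9 items, 0-3).
#' @return `NULL` when item 9 is 0, otherwise a list with `item9_value`.
#' @export
check_alert <- function(items) {
  if (length(items) != 9)
    stop("PHQ-9 has 9 items", call. = FALSE)
  if (is.na(items[9]) || items[9] < 1) return(NULL)
  list(item9_value = as.integer(items[9]))
}

#' Score all instrument responses in a long-format table
#'
#' Groups the long table by participant, day and instrument, validates and
#' scores each response, and audits PHQ-9 item 9 for alerts. Incomplete
#' responses (wrong item count or out-of-range items) are excluded and
#' logged, never prorated.
#'
#' @param instruments Long table `participant_id`, `day_index`,
#'   `instrument`, `item_index`, `value`.
#' @return A list with `scores` (`participant_id`, `day_index`,
#'   `instrument`, `total`), `alerts` (`participant_id`, `day_index`,
#'   `item9_value`), and `excluded` (response keys with reasons).
#' @export
score_responses <- function(instruments) {
  key <- interaction(instruments$participant_id, instruments$day_index,
                     instruments$instrument, drop = TRUE)
  scores <- list(); alerts <- list(); excluded <- list()
  for (k in levels(key)) {
    r <- instruments[key == k, ]
    r <- r[order(r$item_index), ]
    pid <- r$participant_id[1]; day <- r$day_index[1]; inst <- r$instrument[1]
    total <- tryCatch(score_instrument(inst, r$value), error = function(e) e)
    if (inherits(total, "error")) {
      excluded[[length(excluded) + 1]] <- data.frame(
        participant_id = pid, day_index = day, instrument = inst,
        reason = conditionMessage(total), stringsAsFactors = FALSE)
      next
    }
    scores[[length(scores) + 1]] <- data.frame(
      participant_id = pid, day_index = day, instrument = inst,
      total = total, stringsAsFactors = FALSE)
    if (inst == "PHQ9") {
      al <- check_alert(r$value)
      if (!is.null(al)) {
        alerts[[length(alerts) + 1]] <- data.frame(
          participant_id = pid, day_index = day,
          item9_value = al$item9_value, stringsAsFactors = FALSE)
      }
    }
  }
  empty <- function(...) data.frame(..., stringsAsFactors = FALSE)
  list(
    scores = if (length(scores)) do.call(rbind, scores) else
      empty(participant_id = character(), day_index = integer(),
            instrument = character(), total = integer()),
    alerts = if (length(alerts)) do.call(rbind, alerts) else
      empty(participant_id = character(), day_index = integer(),
            item9_value = integer()),
    excluded = if (length(excluded)) do.call(rbind, excluded) else
      empty(participant_id = character(), day_index = integer(),
            instrument = character(), reason = character())
  )
}

#' Frequency of top-level ("very stressed") daily reports
#'
#' Fraction of completed daily stress surveys reporting the maximum stress
#' level. Participants with no completed surveys yield `NA` and are meant
#' to be excluded from group tests rather than counted as zero.
#'
#' @param completed Logical vector of survey completion.
#' @param stress_level Ordinal stress (0-3), `NA` when not completed.
#' @param max_level Top level of the scale (default 3).
#' @return Fraction in `[0, 1]`, or `NA` when nothing was completed.
#' @export
stress_frequency <- function(completed, stress_level, max_level = 3) {
  done <- !is.na(completed) & completed
  if (sum(done) == 0) return(NA_real_)
  mean(stress_level[done] == max_level, na.rm = TRUE)
}

#' Rolling-mean score matrix per instrument
#'
#' For each participant and instrument, the centered rolling mean of totals
#' over responses falling within `window_days` of each study day; days with
#' no in-window response are `NA`. The long result is the data behind
#' participant-by-day heat maps of psychosocial state.
#'
#' @param scores `scores` table from [score_responses()].
#' @param window_days Full window width in days (default 28).
#' @param horizon_days Day grid length (default 180).
#' @return Long data.frame `participant_id`, `instrument`, `day_index`,
#'   `rolling_mean`.
#' @export
rolling_score_matrix <- function(scores, window_days = 28, horizon_days = 180) {
  h <- window_days / 2
  grid <- 0:(horizon_days - 1)
  out <- list()
  for (pid in unique(scores$participant_id)) {
    for (inst in unique(scores$instrument)) {
      s <- scores[scores$participant_id == pid & scores$instrument == inst, ]
      if (nrow(s) == 0) next
      rm_ <- vapply(grid, function(t) {
        sel <- abs(s$day_index - t) <= h
        if (!any(sel)) NA_real_ else mean(s$total[sel])
      }, numeric(1))
      out[[length(out) + 1]] <- data.frame(
        participant_id = pid, instrument = inst, day_index = grid,
        rolling_mean = rm_, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(participant_id = character(), instrument = character(),
                      day_index = integer(), rolling_mean = numeric()))
  }
  do.call(rbind, out)
}

#' Welch group comparisons of instrument scores
#'
#' Aggregates to one value per participant per instrument (the mean of that
#' participant's totals) before testing, so group tests have n =
#' participants rather than n = responses. Strata with fewer than two
#' participants are flagged with an `NA` test rather than dropped.
#'
#' @param scores `scores` table from [score_responses()].
#' @param participants Participant table with strata columns.
#' @param strata Stratum column names to compare.
#' @return A data.frame `instrument`, `stratum`, group labels and means,
#'   `t`, `df`, `p` (all `NA` and `flagged = TRUE` when a group is too
#'   small).
#' @export
score_group_compare <- function(scores, participants,
                                strata = c("age_group", "tp53_status",
                                           "cancer_history")) {
  per <- aggregate(total ~ participant_id + instrument, data = scores,
                   FUN = mean)
  m <- merge(per, participants, by = "participant_id")
  rows <- list()
  for (inst in unique(m$instrument)) {
    for (st in strata) {
      lvls <- sort(unique(as.character(m[[st]])), decreasing = TRUE)
      if (length(lvls) != 2) next
      a <- m$total[m$instrument == inst & as.character(m[[st]]) == lvls[1]]
      b <- m$total[m$instrument == inst & as.character(m[[st]]) == lvls[2]]
      if (length(a) < 2 || length(b) < 2) {
        rows[[length(rows) + 1]] <- data.frame(
          instrument = inst, stratum = st, group_a = lvls[1],
          group_b = lvls[2], mean_a = if (length(a)) mean(a) else NA_real_,
          mean_b = if (length(b)) mean(b) else NA_real_,
          t = NA_real_, df = NA_real_, p = NA_real_, flagged = TRUE,
          stringsAsFactors = FALSE)
        next
      }
      w <- welch_t(a, b)
      rows[[length(rows) + 1]] <- data.frame(
        instrument = inst, stratum = st, group_a = lvls[1], group_b = lvls[2],
        mean_a = w$group_means[1], mean_b = w$group_means[2],
        t = w$t_statistic, df = w$df, p = w$p_value, flagged = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
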