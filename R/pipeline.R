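#' Run configuration for the end-to-end pipeline
#'
#' Bundles input location (or a simulation configuration), analysis
#' thresholds and the output directory. Every threshold defaults to the
#' primary analysis value: 6 h wear threshold, 180-day horizon, 7-day
#' smoothing window, top-3 dominant periods, 3-day modeling window, 5 CV
#' folds, >= 2 scans and >= 300 h look-back wear for scan-event eligibility.
#'
#' @param input_dir Directory of cohort CSVs (see [write_cohort()]); `NULL`
#'   to simulate with `cohort`.
#' @param cohort A [cohort_config()] used when `input_dir` is `NULL`.
#' @param out_dir Output directory.
#' @param threshold_hours,horizon_days,window,fft_k,window_days,folds,min_scans,min_wear_hours,lookback_days
#'   Analysis thresholds (see module functions).
#' @param strata Stratum columns for group comparisons.
#' @param seed Integer seed for the run.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(input_dir = NULL, cohort = cohort_config(),
                       out_dir = "scanwear-out", threshold_hours = 6,
                       horizon_days = 180, window = 7, fft_k = 3,
                       window_days = 3, folds = 5, min_scans = 2,
                       min_wear_hours = 300, lookback_days = 30,
                       strata = c("age_group", "tp53_status", "cancer_history"),
                       seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

pipeline_log <- function(...) message("[scanwear] ", sprintf(...))

load_cohort_dir <- function(dir) {
  read1 <- function(nm) {
    path <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(path)) stop("missing input file: ", path, call. = FALSE)
    read.csv(path, stringsAsFactors = FALSE)
  }
  list(participants = read1("participants"), daily = read1("daily"),
       scans = read1("scans"), physio = read1("physio"),
       instruments = read1("instruments"))
}

validate_daily <- function(daily) {
  need <- c("participant_id", "day_index", "valid_wear_minutes")
  miss <- setdiff(need, names(daily))
  if (length(miss) > 0)
    stop("daily table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- which(!is.na(daily$valid_wear_minutes) &
                 (daily$valid_wear_minutes < 0 | daily$valid_wear_minutes > 1440))
  if (length(bad) > 0)
    stop("daily row ", bad[1], ": valid_wear_minutes outside [0, 1440]",
         call. = FALSE)
  invisible(daily)
}

#' Run the analysis pipeline
#'
#' Orchestrates the full workflow. Subcommands: `"simulate"` writes the
#' synthetic cohort CSVs; `"engagement"`, `"retention"`, `"periodicity"`,
#' `"scores"`, `"scanxiety"` run one analysis stage and write its tables;
#' `"all"` runs everything and assembles a markdown report. Stages
#' communicate only through the documented file schemas, so any stage can
#' be replayed from files. A `manifest.json` (config echo, seed, row
#' counts, package version) is written with every run.
#'
#' @param subcommand One of `"simulate"`, `"engagement"`, `"retention"`,
#'   `"periodicity"`, `"scores"`, `"scanxiety"`, `"all"`.
#' @param config A [run_config()].
#' @return Invisibly, a list of the computed objects.
#' @export
run_pipeline <- function(subcommand = c("all", "simulate", "engagement",
                                        "retention", "periodicity", "scores",
                                        "scanxiety"),
                         config = run_config()) {
  subcommand <- match.arg(subcommand)
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  set.seed(config$seed)
  if (is.null(config$input_dir)) {
    cohort_cfg <- config$cohort
    if (is.null(cohort_cfg$seed)) cohort_cfg$seed <- config$seed
    pipeline_log("simulating cohort: %d children + %d adults over %d days",
                 cohort_cfg$n_children, cohort_cfg$n_adults,
                 cohort_cfg$horizon_days)
    cohort <- simulate_cohort(cohort_cfg)
    if (subcommand %in% c("simulate", "all")) {
      write_cohort(cohort, out)
      pipeline_log("wrote cohort tables (%d daily rows, %d physio rows)",
                   nrow(cohort$daily), nrow(cohort$physio))
    }
  } else {
    cohort <- load_cohort_dir(config$input_dir)
  }
  validate_daily(cohort$daily)
  results <- list(cohort = cohort)
  counts <- list(participants = nrow(cohort$participants),
                 daily = nrow(cohort$daily), physio = nrow(cohort$physio))
  wcsv <- function(df, nm) {
    if (!is.null(df)) write.csv(df, file.path(out, paste0(nm, ".csv")),
                                row.names = FALSE)
  }

  if (subcommand %in% c("engagement", "all")) {
    summ <- engagement_summary(cohort$daily, config$threshold_hours,
                               config$window, horizon_days = config$horizon_days)
    tests <- engagement_group_tests(summ, cohort$participants, config$strata)
    wear_tab <- wear_time_summary(cohort$daily, cohort$participants,
                                  "age_group", config$threshold_hours,
                                  horizon_days = config$horizon_days)
    wcsv(summ, "engagement_summary"); wcsv(tests, "group_tests")
    wcsv(wear_tab, "wear_time_summary")
    pipeline_log("engagement: %d participant-modality rates; %d group tests",
                 nrow(summ), nrow(tests))
    results$engagement <- list(summary = summ, tests = tests,
                               wear_table = wear_tab)
  }

  if (subcommand %in% c("retention", "all")) {
    surv_list <- list(); km_curves <- list(); km_medians <- list(); lr <- list()
    for (mod in c("watch", "survey")) {
      rec <- survival_records(cohort$daily, cohort$participants, mod,
                              config$threshold_hours, config$horizon_days)
      surv_list[[mod]] <- rec
      pipeline_log("%s day-state series: %d exits, %d censored", mod,
                   sum(rec$event), sum(!rec$event))
      for (st in config$strata) {
        km <- km_fit(rec, st)
        km_curves[[paste(mod, st)]] <- data.frame(modality = mod,
                                                  strat_var = st, km$curve)
        km_medians[[paste(mod, st)]] <- data.frame(modality = mod,
                                                   strat_var = st, km$summary)
        t_ <- tryCatch(log_rank(rec, st), error = function(e) NULL)
        if (!is.null(t_)) {
          lr[[paste(mod, st)]] <- data.frame(
            modality = mod, stratum = st, chisq = t_$chisq, df = t_$df,
            p = t_$p_value, stringsAsFactors = FALSE)
        }
      }
    }
    surv_all <- do.call(rbind, surv_list)
    wcsv(surv_all, "survival_records")
    wcsv(do.call(rbind, km_curves), "km_curves")
    wcsv(do.call(rbind, km_medians), "km_medians")
    wcsv(do.call(rbind, lr), "log_rank_tests")
    results$retention <- list(records = surv_all,
                              medians = do.call(rbind, km_medians),
                              log_rank = do.call(rbind, lr))
  }

  if (subcommand %in% c("periodicity", "all")) {
    spec <- cohort_spectra(cohort$daily, config$threshold_hours,
                           config$window, config$fft_k)
    wcsv(spec$spectra, "spectra"); wcsv(spec$dominant, "dominant_periods")
    if (!is.null(spec$dominant)) {
      wcsv(period_histogram(spec$dominant), "period_histogram")
      pipeline_log("periodicity: dominant periods for %d series",
                   length(unique(paste(spec$dominant$participant_id,
                                       spec$dominant$modality))))
    }
    results$periodicity <- spec
  }

  if (subcommand %in% c("scores", "all")) {
    sc <- score_responses(cohort$instruments)
    stress <- do.call(rbind, lapply(
      split(cohort$daily, cohort$daily$participant_id), function(d) {
        data.frame(participant_id = d$participant_id[1],
                   very_stressed_freq = stress_frequency(d$completed,
                                                         d$stress_level),
                   stringsAsFactors = FALSE)
      }))
    rolling <- rolling_score_matrix(sc$scores, horizon_days = config$horizon_days)
    tests <- score_group_compare(sc$scores, cohort$participants, config$strata)
    wcsv(sc$scores, "scores"); wcsv(sc$alerts, "alerts")
    wcsv(stress, "stress_frequency"); wcsv(rolling, "rolling_scores")
    wcsv(tests, "score_group_tests")
    pipeline_log("scores: %d totals, %d alerts from %d participants",
                 nrow(sc$scores), nrow(sc$alerts),
                 length(unique(sc$alerts$participant_id)))
    results$scores <- list(scores = sc$scores, alerts = sc$alerts,
                           stress = stress, tests = tests)
  }

  if (subcommand %in% c("scanxiety", "all")) {
    sx <- scanxiety_analysis(cohort$participants, cohort$scans, cohort$daily,
                             cohort$physio, config$window_days, config$folds,
                             config$min_scans, config$min_wear_hours,
                             config$lookback_days)
    pipeline_log("scanxiety: %d eligible events, %d fitted",
                 nrow(sx$eligible), length(sx$fits))
    for (sid in names(sx$fits)) {
      f <- sx$fits[[sid]]
      write_json(list(scan_id = sid, participant_id = f$participant_id,
                      n = f$n, smoothing = as.list(f$smoothing),
                      cv_mse = sx$cv$cv_mse[sx$cv$scan_id == sid],
                      pdp = f$pdp),
                 file.path(out, paste0("gam_fit_", sid, ".json")),
                 auto_unbox = TRUE, digits = NA)
    }
    wcsv(sx$similarity, "pdp_similarity"); wcsv(sx$cv, "gam_cv")
    results$scanxiety <- sx
  }

  manifest <- list(package = "scanwear",
                   version = as.character(utils::packageVersion("scanwear")),
                   subcommand = subcommand, seed = config$seed,
                   thresholds = config[c("threshold_hours", "horizon_days",
                                         "window", "fft_k", "window_days",
                                         "folds", "min_scans",
                                         "min_wear_hours", "lookback_days")],
                   row_counts = counts)
  write_json(manifest, file.path(out, "manifest.json"), auto_unbox = TRUE,
             digits = NA)
  if (subcommand == "all") write_report(results, out)
  invisible(results)
}

fmt_msd <- function(m, s) sprintf("%.1f (%.1f)", m, s)

write_report <- function(results, out) {
  lines <- c("# Wearable digital-health cohort report", "")
  p <- results$cohort$participants
  lines <- c(lines, "## Cohort",
             sprintf("- %d participants: %d children, %d adults", nrow(p),
                     sum(p$age_group == "child"), sum(p$age_group == "adult")),
             sprintf("- TP53 carriers: %d; cancer history: %d",
                     sum(p$tp53_status == "mut"), sum(p$cancer_history)), "")
  if (!is.null(results$engagement)) {
    wt <- results$engagement$wear_table
    lines <- c(lines, "## Engagement (wear-time table)")
    for (i in seq_len(nrow(wt))) {
      lines <- c(lines, sprintf(
        "- %s (n=%d): days worn %s%%, wear %s h, sleep %s h, awake %s h",
        wt[i, 1], wt$n[i],
        fmt_msd(wt$pct_days_worn_mean[i], wt$pct_days_worn_sd[i]),
        fmt_msd(wt$wear_hours_mean[i], wt$wear_hours_sd[i]),
        fmt_msd(wt$sleep_hours_mean[i], wt$sleep_hours_sd[i]),
        fmt_msd(wt$awake_hours_mean[i], wt$awake_hours_sd[i])))
    }
    gt <- results$engagement$tests
    lines <- c(lines, "", "## Engagement group comparisons (Welch)")
    for (i in seq_len(nrow(gt))) {
      lines <- c(lines, sprintf("- %s / %s: %s %.2f vs %s %.2f, t(%.1f)=%.2f, p=%.3f",
                                gt$stratum[i], gt$modality[i], gt$group_a[i],
                                gt$mean_a[i], gt$group_b[i], gt$mean_b[i],
                                gt$df[i], gt$t[i], gt$p[i]))
    }
    lines <- c(lines, "")
  }
  if (!is.null(results$retention)) {
    md <- results$retention$medians
    lines <- c(lines, "## Retention (Kaplan-Meier medians)")
    for (i in seq_len(nrow(md))) {
      lines <- c(lines, sprintf(
        "- %s / %s = %s (n=%d): median %s d (IQR %s-%s; 95%% CI %s-%s)",
        md$modality[i], md$strat_var[i], md$stratum[i], md$n[i],
        format(md$median[i]), format(md$iqr_lower[i]), format(md$iqr_upper[i]),
        format(md$median_ci_lower[i]), format(md$median_ci_upper[i])))
    }
    lr <- results$retention$log_rank
    lines <- c(lines, "", "## Retention log-rank tests")
    for (i in seq_len(nrow(lr))) {
      lines <- c(lines, sprintf("- %s by %s: chi-square(%d) = %.2f, p = %.3f",
                                lr$modality[i], lr$stratum[i], lr$df[i],
                                lr$chisq[i], lr$p[i]))
    }
    lines <- c(lines, "")
  }
  if (!is.null(results$periodicity) && !is.null(results$periodicity$dominant)) {
    top1 <- results$periodicity$dominant
    top1 <- top1[top1$rank == 1, ]
    lines <- c(lines, "## Periodicity",
               sprintf("- %d series analyzed; median top period %.1f days",
                       nrow(top1), median(top1$period_days)), "")
  }
  if (!is.null(results$scores)) {
    st <- results$scores$tests
    lines <- c(lines, "## Psychosocial scores (Welch group tests)")
    for (i in seq_len(nrow(st))) {
      if (isTRUE(st$flagged[i])) next
      lines <- c(lines, sprintf(
        "- %s by %s: %s %.1f vs %s %.1f, t(%.1f)=%.2f, p=%.3f",
        st$instrument[i], st$stratum[i], st$group_a[i], st$mean_a[i],
        st$group_b[i], st$mean_b[i], st$df[i], st$t[i], st$p[i]))
    }
    al <- results$scores$alerts
    lines <- c(lines, "", "## Self-harm alert audit",
               sprintf("- %d alert(s) from %d participant(s)", nrow(al),
                       length(unique(al$participant_id))), "")
  }
  if (!is.null(results$scanxiety)) {
    sx <- results$scanxiety
    lines <- c(lines, "## Scan-proximity physiology (GAM)",
               sprintf("- eligible events: %d across %d participants",
                       nrow(sx$eligible),
                       length(unique(sx$eligible$participant_id))),
               sprintf("- fitted events: %d", length(sx$fits)))
    if (!is.null(sx$similarity)) {
      lines <- c(lines, sprintf(
        "- within-person partial-dependence similarity: median r = %.2f over %d curve pairs",
        median(sx$similarity$pearson_r, na.rm = TRUE), nrow(sx$similarity)))
    }
    lines <- c(lines, "")
  }
  writeLines(lines, file.path(out, "report.md"))
}
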