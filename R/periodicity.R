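#' Mean-subtract a series
#'
#' Subtracts the sample mean computed over non-missing values; missing
#' values stay missing. The non-missing mean of the output is exactly zero.
#'
#' @param x Numeric series, possibly with `NA`.
#' @return Detrended series of the same length.
#' @export
detrend <- function(x) {
  obs <- !is.na(x)
  if (sum(obs) < 2) stop("need at least 2 finite values to detrend", call. = FALSE)
  x - mean(x[obs])
}

#' FFT periodogram of an engagement series
#'
#' Real-input FFT magnitudes at positive frequencies, with frequencies
#' converted to periods in days: `period = N / k` for bin `k = 1..floor(N/2)`
#' where `N` is the series length. The series is expected detrended;
#' missing values are zero-filled after detrending (unbiased under
#' missingness that is independent of the signal), so the zero-frequency
#' term vanishes and is excluded.
#'
#' @param x Detrended daily series (length `N >= 4`); `NA` allowed.
#' @return An object of class `spectrum_days`: data.frame `period_days`
#'   (descending) and `magnitude`, with attribute `n` = series length.
#' @examples
#' s <- detrend(cos(2 * pi * (0:167) / 14))
#' head(periodogram(s))
#' @export
periodogram <- function(x) {
  n <- length(x)
  if (n < 4) stop("series too short for a periodogram (N < 4)", call. = FALSE)
  x <- ifelse(is.na(x), 0, x)
  X <- fft(x)
  k <- seq_len(floor(n / 2))
  out <- data.frame(period_days = n / k, magnitude = Mod(X[k + 1]))
  attr(out, "n") <- n
  class(out) <- c("spectrum_days", "data.frame")
  out
}

#' Dominant periods of a spectrum
#'
#' The `k` largest-magnitude spectral bins, magnitude-descending; magnitude
#' ties break toward the longer period.
#'
#' @param spec Output of [periodogram()].
#' @param k Number of dominant periods to keep (default 3).
#' @return A data.frame `rank`, `period_days`, `magnitude`.
#' @export
dominant_periods <- function(spec, k = 3) {
  if (nrow(spec) == 0) stop("empty spectrum", call. = FALSE)
  ord <- order(-spec$magnitude, -spec$period_days)
  top <- spec[utils::head(ord, k), , drop = FALSE]
  data.frame(rank = seq_len(nrow(top)), period_days = top$period_days,
             magnitude = top$magnitude, row.names = NULL)
}

#' Cohort-level spectral analysis of smoothed engagement
#'
#' For each participant and modality with at least `min_days` observed days,
#' detrends the smoothed series, computes the periodogram and extracts the
#' top dominant periods. The 28-day minimum gives two full cycles of the
#' shortest reportable (biweekly) period.
#'
#' @param daily Daily table (see [engagement_series()]).
#' @param threshold_hours Watch activity threshold in hours.
#' @param window Smoothing window (days, odd).
#' @param k Dominant periods per series.
#' @param min_days Minimum series length for inclusion (default 28).
#' @return A list with `spectra` (long data.frame of all bins) and
#'   `dominant` (participant, modality, rank, period_days, magnitude).
#' @export
cohort_spectra <- function(daily, threshold_hours = 6, window = 7, k = 3,
                           min_days = 28) {
  series <- engagement_series(daily, threshold_hours, window)
  spectra <- list(); dom <- list()
  for (pid in names(series)) {
    for (mod in c("watch", "survey")) {
      sm <- series[[pid]][[mod]]$smoothed
      if (length(sm) < min_days || sum(!is.na(sm)) < 2) next
      d <- detrend(sm)
      if (all(d[!is.na(d)] == 0)) next # constant engagement has no spectrum
      sp <- periodogram(d)
      spectra[[length(spectra) + 1]] <- data.frame(
        participant_id = pid, modality = mod, sp, stringsAsFactors = FALSE)
      dp <- dominant_periods(sp, k)
      dom[[length(dom) + 1]] <- data.frame(
        participant_id = pid, modality = mod, dp, stringsAsFactors = FALSE)
    }
  }
  list(
    spectra = if (length(spectra)) do.call(rbind, spectra) else NULL,
    dominant = if (length(dom)) do.call(rbind, dom) else NULL
  )
}

#' Histogram of dominant periods in weeks
#'
#' Bins the top dominant periods across participants into whole weeks, the
#' cohort-level summary used to spot biweekly/monthly engagement cycles.
#'
#' @param dominant `dominant` table from [cohort_spectra()].
#' @param max_weeks Longest bin, weeks.
#' @return A data.frame `weeks`, `count`.
#' @export
period_histogram <- function(dominant, max_weeks = 13) {
  wk <- pmin(ceiling(dominant$period_days / 7), max_weeks)
  tab <- table(factor(wk, levels = seq_len(max_weeks)))
  data.frame(weeks = as.integer(names(tab)), count = as.integer(tab))
}
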