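# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# two-pass day-state rule: label every nonactive day "exit", then reclassify
# as "inactive" any exit day followed (at any later day) by an active day
oracle_states <- function(active) {
  n <- length(active)
  states <- ifelse(active, "active", "exit")
  for (i in seq_len(n)) {
    if (states[i] == "exit" && any(active[seq_len(n) > i])) {
      states[i] <- "inactive"
    }
  }
  states
}

oracle_exit <- function(states, horizon = 180) {
  n <- length(states)
  exit_idx <- which(states == "exit")
  if (length(exit_idx) == 0) {
    return(list(time_days = min(n, horizon), event = FALSE))
  }
  t <- min(exit_idx) - 1 # 0-based first day of the terminal run
  if (t <= horizon) list(time_days = t, event = TRUE)
  else list(time_days = min(n, horizon), event = FALSE)
}

# product-limit estimator by direct computation
oracle_km <- function(times, events) {
  ts <- sort(unique(times[events]))
  surv <- numeric(length(ts))
  s <- 1
  for (i in seq_along(ts)) {
    t <- ts[i]
    n_risk <- sum(times >= t)
    d <- sum(times == t & events)
    s <- s * (1 - d / n_risk)
    surv[i] <- s
  }
  data.frame(time = ts, survival = surv)
}

# two-sample log-rank chi-square via per-event-time hypergeometric moments
oracle_logrank <- function(times, events, group) {
  g1 <- group == sort(unique(group))[1]
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(times[events]))) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g1)
    d <- sum(times == t & events)
    d1 <- sum(times == t & events & g1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# closed-form Welch t, Satterthwaite df, two-sided p
oracle_welch <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- var(a); vb <- var(b)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# direct DFT magnitude at positive-frequency bins
oracle_dft <- function(x) {
  n <- length(x)
  ks <- seq_len(floor(n / 2))
  vapply(ks, function(k) {
    t <- 0:(n - 1)
    Mod(sum(x * exp(-2i * pi * k * t / n)))
  }, numeric(1))
}

# enumerate all boolean sequences of a given length
all_bool_sequences <- function(len) {
  grid <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), len)))
  lapply(seq_len(nrow(grid)), function(i) unname(grid[i, ]))
}

# small deterministic cohort for integration-style tests
small_cohort <- function(seed = 11, n_children = 4, n_adults = 8, ...) {
  simulate_cohort(cohort_config(n_children = n_children, n_adults = n_adults,
                                seed = seed, ...))
}
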