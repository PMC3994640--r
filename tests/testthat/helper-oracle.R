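# Independent oracles and random-case generators shared across tests.

# Criterion mapping re-stated from the clinical rule itself (thresholds
# hard-coded on purpose: this must not depend on criteria_config or
# evaluate_criterion).
oracle_criterion <- function(kind, value) {
  if (kind == "TEMPERATURE") {
    if (value <= 36 || value >= 38) return("SIRS_TEMP")
  } else if (kind == "HEART_RATE") {
    if (value >= 90) return("SIRS_HR")
  } else if (kind == "RESPIRATORY_RATE") {
    if (value >= 20) return("SIRS_RR")
  } else if (kind == "WBC_COUNT") {
    if (value <= 4000 || value >= 12000) return("SIRS_WBC")
  } else if (kind == "BANDS_PERCENT") {
    if (value > 10) return("SIRS_WBC")
  } else if (kind == "SYSTOLIC_BP") {
    if (value <= 90) return("SHOCK_SBP")
  } else if (kind == "LACTATE") {
    if (value >= 2.0) return("SHOCK_LACTATE")
  }
  NA_character_
}

# Brute-force reference for the alert engine: for every batch prefix,
# recompute the satisfied-criteria set from scratch and emit an alert at
# each prefix where the joint condition (>=2 SIRS + >=1 shock) holds and
# the set strictly grew over the previous prefix (or first became
# sufficient).
oracle_alerts <- function(e) {
  obs <- e$observations
  if (nrow(obs) == 0) return(list())
  batches <- split(seq_len(nrow(obs)),
                   factor(as.numeric(obs$timestamp),
                          levels = unique(as.numeric(obs$timestamp))))
  alerts <- list()
  prev_set <- character()
  active <- FALSE
  for (b in seq_along(batches)) {
    idx <- unlist(batches[seq_len(b)])
    cur_set <- character()
    for (i in idx) {
      c_i <- oracle_criterion(obs$kind[i], obs$value[i])
      if (!is.na(c_i)) cur_set <- union(cur_set, c_i)
    }
    sirs_n <- sum(cur_set %in% c("SIRS_TEMP", "SIRS_HR", "SIRS_RR", "SIRS_WBC"))
    shock_n <- sum(cur_set %in% c("SHOCK_SBP", "SHOCK_LACTATE"))
    cond <- sirs_n >= 2 && shock_n >= 1
    grew <- length(setdiff(cur_set, prev_set)) > 0
    if (cond && ((!active) || grew)) {
      alerts[[length(alerts) + 1L]] <- list(
        time = obs$timestamp[batches[[b]][1]],
        set = sort(cur_set))
      active <- TRUE
    }
    if (cond) active <- TRUE
    prev_set <- cur_set
  }
  alerts
}

# Random observation stream of <= max_n observations: values straddle the
# thresholds, timestamps may tie so same-timestamp batching is exercised.
random_stream_encounter <- function(id, max_n = 12) {
  n <- sample.int(max_n, 1)
  kinds <- sample(observation_kinds(), n, replace = TRUE)
  t0 <- as.POSIXct("2012-02-01 08:00:00", tz = "UTC")
  times <- t0 + sort(sample(0:7, n, replace = TRUE)) * 600
  value <- vapply(kinds, function(k) {
    switch(k,
      TEMPERATURE      = stats::runif(1, 34.5, 39.5),
      HEART_RATE       = stats::runif(1, 60, 130),
      RESPIRATORY_RATE = stats::runif(1, 10, 30),
      SYSTOLIC_BP      = stats::runif(1, 70, 140),
      WBC_COUNT        = stats::runif(1, 2000, 16000),
      BANDS_PERCENT    = stats::runif(1, 0, 20),
      LACTATE          = stats::runif(1, 0.5, 4))
  }, 0)
  encounter(id, observations(times, kinds, value))
}

# TRUE iff engine output equals the oracle (times, counts, criteria sets).
matches_oracle <- function(e, cfg = criteria_config()) {
  eng <- process_encounter(e, cfg)
  ora <- oracle_alerts(e)
  if (nrow(eng) != length(ora)) return(FALSE)
  for (j in seq_along(ora)) {
    if (!identical(as.numeric(eng$activation_time[j]),
                   as.numeric(ora[[j]]$time))) return(FALSE)
    eng_set <- sort(c(strsplit(eng$satisfied_sirs[j], ";")[[1]],
                      strsplit(eng$satisfied_shock[j], ";")[[1]]))
    if (!identical(eng_set[nzchar(eng_set)], ora[[j]]$set)) return(FALSE)
  }
  TRUE
}

# Compare engine output against the oracle for one encounter.
expect_matches_oracle <- function(e, cfg = criteria_config()) {
  eng <- process_encounter(e, cfg)
  ora <- oracle_alerts(e)
  expect_equal(nrow(eng), length(ora))
  if (nrow(eng) == length(ora) && length(ora) > 0) {
    for (j in seq_along(ora)) {
      expect_identical(eng$activation_time[j], ora[[j]]$time)
      eng_set <- sort(c(strsplit(eng$satisfied_sirs[j], ";")[[1]],
                        strsplit(eng$satisfied_shock[j], ";")[[1]]))
      expect_identical(eng_set[nzchar(eng_set)], ora[[j]]$set)
    }
  }
  invisible(NULL)
}

# Clopper-Pearson bounds by bisection on the binomial tail CDF, independent
# of qbeta.
oracle_clopper_pearson <- function(x, n, level = 0.95, tol = 1e-10) {
  a <- (1 - level) / 2
  bisect <- function(f, lo, hi) {
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) hi <- mid else lo <- mid
      if (hi - lo < tol) break
    }
    (lo + hi) / 2
  }
  lower <- if (x == 0) 0 else
    bisect(function(p) stats::pbinom(x - 1, n, p, lower.tail = FALSE) - a, 0, x / n)
  upper <- if (x == n) 1 else
    bisect(function(p) a - stats::pbinom(x, n, p), x / n, 1)
  c(lower = lower, upper = upper)
}
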