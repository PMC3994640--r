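# Seeded generator of labelled synthetic ED encounters. Alert-target
# encounters are built constructively (the chosen criteria are injected
# into an otherwise-normal vital/lab trajectory), non-alert encounters by
# rejection against the alert engine itself, so label purity is guaranteed
# by construction rather than by distributional argument.

# Category->probability calibration maps: the observed per-category shares
# among true-positive, false-positive and sampled non-alert patients of a
# three-month single-centre ED screening study. Multi-label: treated as
# independent per-category Bernoulli probabilities.
default_category_mix_tp <- function() {
  c(pneumonia_respiratory = 0.380, urinary_tract = 0.327,
    gastrointestinal = 0.152, bacteremia = 0.138, cellulitis = 0.093,
    abscess = 0.073, gynecologic = 0.014, cns = 0.009, other = 0.034)
}

default_category_mix_fp <- function() {
  c(gastrointestinal = 0.261, trauma = 0.257, cardiovascular = 0.200,
    respiratory = 0.098, overdose_intoxication = 0.096, cns = 0.089,
    renal = 0.077, hematologic_oncologic = 0.034, other = 0.271)
}

default_category_mix_tn <- function() {
  c(urinary_tract_infection = 0.090, respiratory_infection = 0.083,
    abscess = 0.027, cellulitis = 0.017, gastrointestinal_infection = 0.013,
    gynecologic_infection = 0.013, other_infection = 0.070,
    trauma = 0.140, gastrointestinal = 0.100, cns = 0.053,
    overdose_intoxication = 0.037, cardiovascular = 0.027,
    respiratory = 0.010, renal = 0.013, hematologic_oncologic = 0.003,
    other = 0.453)
}

default_disposition_probs <- function() {
  list(TRUE_POSITIVE  = c(ADMITTED = 0.910, DIED_IN_ED = 0.003, DISCHARGED = 0.087),
       FALSE_POSITIVE = c(ADMITTED = 0.830, DIED_IN_ED = 0.002, DISCHARGED = 0.168),
       TRUE_NEGATIVE  = c(ADMITTED = 0.057, DIED_IN_ED = 0.000, DISCHARGED = 0.943))
}

#' Specification for a synthetic ED cohort
#'
#' Defaults reproduce the statistical structure the evaluation assumes:
#' 795 alert-firing encounters of which a fraction `ppv_target = 0.447`
#' are truly septic, 300 sampled never-alerting encounters, category mixes
#' and disposition probabilities matching the observed shares, and
#' `extra_criteria_rate = 0.8` — the mean of the (capped) Poisson number of
#' additional criteria fulfilled after the first alert, calibrated so the
#' per-patient alert count has median 2 and IQR \[1, 2\].
#'
#' @param n_alert_target Number of encounters built to fire >= 1 alert.
#' @param ppv_target Probability an alert-firing encounter is labelled
#'   septic.
#' @param n_nonalert Number of encounters built never to alert.
#' @param category_mix_tp,category_mix_fp,category_mix_tn Named
#'   category-probability vectors (independent Bernoulli per category).
#' @param disposition_probs Named list of per-group disposition probability
#'   vectors, each summing to 1.
#' @param extra_criteria_rate Mean number of additional criteria fulfilled
#'   after the first alert (Poisson, capped at the number of remaining
#'   criteria); drives repeat-alert counts.
#' @param seed Integer RNG seed; the generator is deterministic given it.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_alert_target = 795, ppv_target = 0.447,
                        n_nonalert = 300,
                        category_mix_tp = default_category_mix_tp(),
                        category_mix_fp = default_category_mix_fp(),
                        category_mix_tn = default_category_mix_tn(),
                        disposition_probs = default_disposition_probs(),
                        extra_criteria_rate = 0.8,
                        seed = 1L) {
  spec <- list(n_alert_target = as.integer(n_alert_target),
               ppv_target = ppv_target, n_nonalert = as.integer(n_nonalert),
               category_mix_tp = category_mix_tp,
               category_mix_fp = category_mix_fp,
               category_mix_tn = category_mix_tn,
               disposition_probs = disposition_probs,
               extra_criteria_rate = extra_criteria_rate,
               seed = as.integer(seed))
  if (spec$n_alert_target < 0 || spec$n_nonalert < 0) {
    stop("encounter counts must be non-negative")
  }
  if (spec$ppv_target < 0 || spec$ppv_target > 1) {
    stop("ppv_target must be a probability")
  }
  for (m in list(category_mix_tp, category_mix_fp, category_mix_tn)) {
    if (any(m < 0 | m > 1)) stop("category probabilities must lie in [0, 1]")
  }
  for (g in names(spec$disposition_probs)) {
    if (abs(sum(spec$disposition_probs[[g]]) - 1) > 1e-6) {
      stop("disposition probabilities for ", g, " must sum to 1")
    }
  }
  if (spec$extra_criteria_rate < 0) stop("extra_criteria_rate must be >= 0")
  class(spec) <- "cohort_spec"
  spec
}

# Criterion-satisfying and normal value draws. Abnormal values are drawn
# uniformly inside the abnormal region with a one-resolution margin off
# the threshold; normal values sit strictly inside normal limits. This
# exercises the rule without pretending to clinical realism.
draw_value <- function(n, kind, abnormal, cfg) {
  r <- function(lo, hi) stats::runif(n, lo, hi)
  if (abnormal) {
    switch(kind,
      TEMPERATURE      = if (stats::runif(1) < 0.8) r(cfg$temp_high + 0.1, 40.5)
                         else r(34.0, cfg$temp_low - 0.1),
      HEART_RATE       = r(cfg$hr_min + 1, 150),
      RESPIRATORY_RATE = r(cfg$rr_min + 1, 40),
      SYSTOLIC_BP      = r(65, cfg$sbp_max - 1),
      WBC_COUNT        = if (stats::runif(1) < 0.8) r(cfg$wbc_high + 100, 25000)
                         else r(500, cfg$wbc_low - 100),
      BANDS_PERCENT    = r(cfg$bands_min_pct + 1, 30),
      LACTATE          = r(cfg$lactate_min + 0.1, 6))
  } else {
    switch(kind,
      TEMPERATURE      = r(cfg$temp_low + 0.2, cfg$temp_high - 0.2),
      HEART_RATE       = r(60, cfg$hr_min - 1),
      RESPIRATORY_RATE = r(12, cfg$rr_min - 1),
      SYSTOLIC_BP      = r(cfg$sbp_max + 10, 140),
      WBC_COUNT        = r(cfg$wbc_low + 500, cfg$wbc_high - 500),
      BANDS_PERCENT    = r(0, cfg$bands_min_pct - 1),
      LACTATE          = r(0.5, cfg$lactate_min - 0.1))
  }
}

criterion_kind <- function(id) {
  switch(id, SIRS_TEMP = "TEMPERATURE", SIRS_HR = "HEART_RATE",
         SIRS_RR = "RESPIRATORY_RATE", SIRS_WBC = "WBC_COUNT",
         SHOCK_SBP = "SYSTOLIC_BP", SHOCK_LACTATE = "LACTATE")
}

# One trajectory: piecewise-constant vitals charted every 30 min over a
# 2-12 h stay, labs (WBC, bands, lactate) drawn once mid-stay.
normal_trajectory <- function(t0, cfg) {
  n_slots <- sample(4:24, 1)
  times <- t0 + 1800 * (seq_len(n_slots) - 1)
  vit <- c("TEMPERATURE", "HEART_RATE", "RESPIRATORY_RATE", "SYSTOLIC_BP")
  obs <- data.frame(
    timestamp = rep(times, each = length(vit)),
    kind = rep(vit, n_slots),
    value = NA_real_, unit = NA_character_, stringsAsFactors = FALSE)
  lab_time <- times[max(2L, n_slots %/% 2L)] + 600
  labs <- data.frame(
    timestamp = rep(lab_time, 3),
    kind = c("WBC_COUNT", "BANDS_PERCENT", "LACTATE"),
    value = NA_real_, unit = NA_character_, stringsAsFactors = FALSE)
  obs <- rbind(obs, labs)
  for (k in unique(obs$kind)) {
    i <- obs$kind == k
    obs$value[i] <- draw_value(sum(i), k, abnormal = FALSE, cfg = cfg)
  }
  obs$unit <- vapply(accepted_units()[obs$kind], `[[`, "", 1, USE.NAMES = FALSE)
  obs[order(obs$timestamp), , drop = FALSE]
}

# Inject criterion ids so that all of `initial` are fulfilled by one anchor
# time (completing the first alert there) and each element of `extras`
# first becomes fulfilled at its own strictly later timestamp, yielding
# exactly one repeat alert apiece under strict-growth semantics.
inject_criteria <- function(obs, initial, extras, cfg) {
  lab_kinds <- c("WBC_COUNT", "BANDS_PERCENT", "LACTATE")
  slots <- sort(unique(obs$timestamp[!obs$kind %in% lab_kinds]))
  anchor <- slots[ceiling(0.6 * length(slots))]
  picked_times <- as.POSIXct(character(), tz = "UTC")
  for (id in initial) {
    k <- criterion_kind(id)
    i <- if (k %in% lab_kinds) {
      which(obs$kind == k)  # single lab draw, whenever it resulted
    } else {
      which(obs$kind == k & obs$timestamp <= anchor)
    }
    pick <- i[length(i)]
    obs$value[pick] <- draw_value(1, k, abnormal = TRUE, cfg = cfg)
    picked_times <- c(picked_times, obs$timestamp[pick])
  }
  t_first <- max(picked_times)
  # fresh timestamps off the 30-min charting grid, one per extra criterion
  for (j in seq_along(extras)) {
    k <- criterion_kind(extras[j])
    obs <- rbind(obs, data.frame(timestamp = t_first + j * 1800 + 900,
                                 kind = k,
                                 value = draw_value(1, k, TRUE, cfg),
                                 unit = accepted_units()[[k]][1],
                                 stringsAsFactors = FALSE))
  }
  obs[order(obs$timestamp), , drop = FALSE]
}

sample_categories <- function(mix) {
  hit <- names(mix)[stats::runif(length(mix)) < mix]
  paste(hit, collapse = ";")
}

#' Generate a labelled synthetic ED cohort
#'
#' Produces `n_alert_target` encounters guaranteed to fire at least one
#' sepsis alert and `n_nonalert` encounters guaranteed never to fire one
#' (some carry a single SIRS criterion or an isolated shock sign, mirroring
#' infected-but-not-septic presentations; purity is enforced by running the
#' alert engine and redrawing any stream that alerts). Alert-firing
#' encounters are labelled septic with probability `ppv_target`; categories
#' and dispositions are drawn from the spec's mixes. Deterministic given
#' `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @param cfg A [criteria_config()]; the generator constructs values
#'   relative to these thresholds.
#' @return List with `encounters` (list of [encounter()]) and `labels`
#'   (`data.frame` with `encounter_id`, `sepsis`, `infection_categories`,
#'   `condition_categories`, `disposition`).
#' @export
generate_cohort <- function(spec = cohort_spec(), cfg = criteria_config()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  t_base <- as.POSIXct("2012-01-03 00:00:00", tz = "UTC")
  n_total <- spec$n_alert_target + spec$n_nonalert
  ids <- sprintf("ENC%05d", seq_len(n_total))
  encounters <- vector("list", n_total)
  labels <- data.frame(encounter_id = ids, sepsis = FALSE,
                       infection_categories = "", condition_categories = "",
                       disposition = NA_character_, stringsAsFactors = FALSE)

  sirs <- sirs_criteria(); shock <- shock_criteria()
  for (i in seq_len(spec$n_alert_target)) {
    t0 <- t_base + stats::runif(1, 0, 85 * 86400)
    obs <- normal_trajectory(t0, cfg)
    first_sirs <- sample(sirs, cfg$sirs_required)
    first_shock <- sample(shock, cfg$shock_required)
    remaining <- setdiff(c(sirs, shock), c(first_sirs, first_shock))
    k_extra <- min(stats::rpois(1, spec$extra_criteria_rate), length(remaining))
    extras <- if (k_extra > 0) sample(remaining, k_extra) else character()
    obs <- inject_criteria(obs, c(first_sirs, first_shock), extras, cfg)
    encounters[[i]] <- encounter(ids[i], obs,
                                 patient_age = round(stats::rnorm(1, 55, 20)))
    septic <- stats::runif(1) < spec$ppv_target
    labels$sepsis[i] <- septic
    grp <- if (septic) "TRUE_POSITIVE" else "FALSE_POSITIVE"
    if (septic) {
      cats <- sample_categories(spec$category_mix_tp)
      if (!nzchar(cats)) cats <- "other"
      labels$infection_categories[i] <- cats
    } else {
      labels$condition_categories[i] <- sample_categories(spec$category_mix_fp)
    }
    p <- spec$disposition_probs[[grp]]
    labels$disposition[i] <- sample(names(p), 1, prob = p)
  }

  for (i in spec$n_alert_target + seq_len(spec$n_nonalert)) {
    repeat {
      t0 <- t_base + stats::runif(1, 0, 85 * 86400)
      obs <- normal_trajectory(t0, cfg)
      u <- stats::runif(1)
      if (u < 0.4) {
        # one SIRS criterion, no shock: infected but not septic
        id <- sample(sirs, 1)
        k <- criterion_kind(id)
        j <- which(obs$kind == k)[1]
        obs$value[j] <- draw_value(1, k, TRUE, cfg)
      } else if (u < 0.5) {
        # isolated shock sign without enough SIRS
        id <- sample(shock, 1)
        k <- criterion_kind(id)
        j <- which(obs$kind == k)[1]
        obs$value[j] <- draw_value(1, k, TRUE, cfg)
      }
      e <- encounter(ids[i], obs, patient_age = round(stats::rnorm(1, 45, 20)))
      if (nrow(process_encounter(e, cfg)) == 0) break
    }
    encounters[[i]] <- e
    labels$condition_categories[i] <- sample_categories(spec$category_mix_tn)
    p <- spec$disposition_probs$TRUE_NEGATIVE
    labels$disposition[i] <- sample(names(p), 1, prob = p)
  }

  for (i in seq_len(n_total)) {
    encounters[[i]]$disposition <- labels$disposition[i]
  }
  list(encounters = encounters, labels = labels)
}
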