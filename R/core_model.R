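#' edsepsis: rule-based ED sepsis alerting and its accuracy evaluation
#'
#' Screens time-stamped emergency-department observation streams for sepsis
#' using SIRS-plus-shock criteria evaluated asynchronously, evaluates the
#' resulting alerts against chart-review labels under a sampled-negatives
#' verification design, and generates labelled synthetic ED cohorts for
#' end-to-end testing.
#'
#' @keywords internal
"_PACKAGE"

# ---- observation vocabulary ------------------------------------------------

#' Observation kinds understood by the screening engine
#'
#' Four vital signs and three laboratory results drive the detection rule:
#' temperature, heart rate, respiratory rate and systolic blood pressure are
#' charted by nursing staff; white-cell count, band percentage and lactate
#' arrive from the laboratory.
#'
#' @return Character vector of the seven recognised observation kinds.
#' @export
observation_kinds <- function() {
  c("TEMPERATURE", "HEART_RATE", "RESPIRATORY_RATE", "SYSTOLIC_BP",
    "WBC_COUNT", "BANDS_PERCENT", "LACTATE")
}

#' Accepted measurement units per observation kind
#'
#' Temperature is accepted in Celsius or Fahrenheit and normalised to
#' Celsius on ingestion; every other kind has a single canonical unit.
#' Lactate's unit string is carried verbatim; its alert threshold is
#' compared in configured units without conversion.
#'
#' @return Named list mapping each observation kind to its accepted unit
#'   strings; the first entry of each element is the canonical unit.
#' @export
accepted_units <- function() {
  list(
    TEMPERATURE      = c("C", "°C", "F", "°F"),
    HEART_RATE       = "beats/min",
    RESPIRATORY_RATE = "breaths/min",
    SYSTOLIC_BP      = "mm Hg",
    WBC_COUNT        = "cells/mm3",
    BANDS_PERCENT    = "percent",
    LACTATE          = "mg/dL"
  )
}

#' Convert a temperature to degrees Celsius
#'
#' @param value Numeric temperature values.
#' @param unit Unit string(s), one of `"C"`, `"°C"`, `"F"`, `"°F"`
#'   (recycled against `value`).
#' @return Numeric values in degrees Celsius.
#' @export
#' @examples
#' to_celsius(98.6, "F") # 37
to_celsius <- function(value, unit) {
  unit <- rep_len(unit, length(value))
  f <- unit %in% c("F", "°F")
  bad <- !f & !unit %in% c("C", "°C")
  if (any(bad)) {
    stop("unknown temperature unit: ", paste(unique(unit[bad]), collapse = ", "))
  }
  ifelse(f, (value - 32) * 5 / 9, value)
}

# ---- criteria configuration ------------------------------------------------

#' Detection-rule thresholds
#'
#' All tunable thresholds of the sepsis alert rule. The defaults are the
#' rule as fielded: a SIRS criterion is temperature \eqn{\le} 36 or
#' \eqn{\ge} 38 degC, respiratory rate \eqn{\ge} 20 breaths/min, heart rate
#' \eqn{\ge} 90 beats/min, or white-cell count \eqn{\le} 4,000 or
#' \eqn{\ge} 12,000 cells/mm3 or > 10% bands (one composite criterion);
#' a shock sign is systolic blood pressure \eqn{\le} 90 mm Hg or lactate
#' \eqn{\ge} 2.0. An alert requires `sirs_required` SIRS criteria plus
#' `shock_required` shock signs, fulfilled at any time points within the
#' encounter.
#'
#' @param temp_low,temp_high Temperature bounds, degC (abnormal at or
#'   beyond either).
#' @param rr_min Respiratory-rate threshold, breaths/min (inclusive).
#' @param hr_min Heart-rate threshold, beats/min (inclusive).
#' @param wbc_low,wbc_high White-cell count bounds, cells/mm3 (inclusive).
#' @param bands_min_pct Band-percentage threshold, percent (strictly above).
#' @param sbp_max Systolic blood-pressure threshold, mm Hg (inclusive).
#' @param lactate_min Lactate threshold, in configured units (inclusive).
#' @param sirs_required Number of distinct SIRS criteria required (1-4).
#' @param shock_required Number of distinct shock signs required (1-2).
#' @return Object of class `criteria_config`.
#' @export
#' @examples
#' cfg <- criteria_config()
#' cfg$temp_high
criteria_config <- function(temp_low = 36.0, temp_high = 38.0,
                            rr_min = 20, hr_min = 90,
                            wbc_low = 4000, wbc_high = 12000,
                            bands_min_pct = 10,
                            sbp_max = 90, lactate_min = 2.0,
                            sirs_required = 2L, shock_required = 1L) {
  cfg <- list(
    temp_low = temp_low, temp_high = temp_high,
    rr_min = rr_min, hr_min = hr_min,
    wbc_low = wbc_low, wbc_high = wbc_high,
    bands_min_pct = bands_min_pct,
    sbp_max = sbp_max, lactate_min = lactate_min,
    sirs_required = as.integer(sirs_required),
    shock_required = as.integer(shock_required)
  )
  class(cfg) <- "criteria_config"
  stopifnot(
    cfg$temp_low < cfg$temp_high,
    cfg$wbc_low < cfg$wbc_high,
    cfg$sirs_required %in% 1:4,
    cfg$shock_required %in% 1:2
  )
  cfg
}

#' @export
print.criteria_config <- function(x, ...) {
  cat("Sepsis alert criteria configuration\n")
  cat(sprintf("  SIRS: temp <=%.1f or >=%.1f C; RR >=%g; HR >=%g; WBC <=%g or >=%g or bands >%g%%\n",
              x$temp_low, x$temp_high, x$rr_min, x$hr_min,
              x$wbc_low, x$wbc_high, x$bands_min_pct))
  cat(sprintf("  Shock: SBP <=%g mm Hg or lactate >=%g\n", x$sbp_max, x$lactate_min))
  cat(sprintf("  Alert: >=%d SIRS + >=%d shock\n", x$sirs_required, x$shock_required))
  invisible(x)
}

# ---- encounter container ---------------------------------------------------

#' Build an observation table
#'
#' Convenience constructor for the observation data frame held by an
#' encounter. Temperatures given in Fahrenheit are normalised to Celsius.
#'
#' @param timestamp `POSIXct` times (any timezone; stored as given).
#' @param kind Observation kinds (see [observation_kinds()]).
#' @param value Numeric measurement values.
#' @param unit Unit strings; defaults to the canonical unit of each kind.
#' @return `data.frame` with columns `timestamp`, `kind`, `value`, `unit`.
#' @export
observations <- function(timestamp, kind, value, unit = NULL) {
  kind <- as.character(kind)
  if (is.null(unit)) {
    unit <- vapply(accepted_units()[kind], function(u) u[[1]], "",
                   USE.NAMES = FALSE)
  }
  obs <- data.frame(timestamp = timestamp, kind = kind,
                    value = as.numeric(value), unit = as.character(unit),
                    stringsAsFactors = FALSE)
  normalize_units(obs)
}

# Normalise temperature rows to Celsius; other kinds are left untouched.
normalize_units <- function(obs) {
  is_f <- obs$kind == "TEMPERATURE" & obs$unit %in% c("F", "°F")
  if (any(is_f)) {
    obs$value[is_f] <- to_celsius(obs$value[is_f], "F")
    obs$unit[is_f] <- "C"
  }
  obs$unit[obs$kind == "TEMPERATURE" & obs$unit == "°C"] <- "C"
  obs
}

#' Construct an ED encounter
#'
#' An encounter is one emergency-department visit: an identifier, the
#' patient's age, a time-ordered stream of observations, and (optionally,
#' for evaluation) the ED disposition. Observations are stably sorted by
#' timestamp on construction, so rows sharing a timestamp keep their
#' ingestion order.
#'
#' @param encounter_id Scalar identifier (coerced to character).
#' @param obs Observation `data.frame` as returned by [observations()].
#' @param patient_age Age in years. Carried for description only: the alert
#'   rule is deliberately not age-adjusted.
#' @param disposition Optional, one of `"ADMITTED"`, `"DIED_IN_ED"`,
#'   `"DISCHARGED"`, or `NA`.
#' @return Object of class `ed_encounter`.
#' @export
encounter <- function(encounter_id, obs, patient_age = NA_real_,
                      disposition = NA_character_) {
  if (nrow(obs) > 0) {
    obs <- obs[order(obs$timestamp), , drop = FALSE]  # stable sort
    rownames(obs) <- NULL
  }
  e <- list(encounter_id = as.character(encounter_id),
            patient_age = as.numeric(patient_age),
            disposition = as.character(disposition),
            observations = obs)
  class(e) <- "ed_encounter"
  e
}

#' @export
print.ed_encounter <- function(x, ...) {
  cat(sprintf("ED encounter %s: %d observations", x$encounter_id,
              nrow(x$observations)))
  if (!is.na(x$disposition)) cat(", disposition ", x$disposition, sep = "")
  cat("\n")
  invisible(x)
}

#' Validate an encounter against its structural invariants
#'
#' Checks that observation timestamps are non-decreasing, kinds are
#' recognised, units are accepted for their kind, and values are finite
#' and non-negative. Validation reports; it never raises.
#'
#' @param e An [encounter()].
#' @return Character vector of violations, empty when the encounter is
#'   well formed. Each violation names the field and rule broken.
#' @export
validate_encounter <- function(e) {
  v <- character()
  if (!inherits(e, "ed_encounter")) {
    return("encounter: not an ed_encounter object")
  }
  obs <- e$observations
  if (nrow(obs) == 0) return(v)
  if (is.unsorted(obs$timestamp)) {
    v <- c(v, "observations$timestamp: not in non-decreasing time order")
  }
  units <- accepted_units()
  unknown <- !obs$kind %in% names(units)
  if (any(unknown)) {
    v <- c(v, sprintf("observations$kind: unknown kind '%s'",
                      unique(obs$kind[unknown])))
  }
  for (i in which(!unknown)) {
    ok <- units[[obs$kind[i]]]
    if (!obs$unit[i] %in% ok) {
      v <- c(v, sprintf(
        "observations$unit: unit '%s' not accepted for %s (accepted: %s)",
        obs$unit[i], obs$kind[i], paste(ok, collapse = ", ")))
    }
  }
  bad_val <- !is.finite(obs$value) | obs$value < 0
  if (any(bad_val)) {
    v <- c(v, sprintf("observations$value: non-finite or negative value at row %d",
                      which(bad_val)[1]))
  }
  if (!is.na(e$disposition) &&
      !e$disposition %in% c("ADMITTED", "DIED_IN_ED", "DISCHARGED")) {
    v <- c(v, sprintf("disposition: '%s' not one of ADMITTED/DIED_IN_ED/DISCHARGED",
                      e$disposition))
  }
  v
}
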