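# Stateless evaluation of single observations against the detection rule.
#
# Criterion identifiers. SIRS_WBC is a single composite criterion with two
# satisfying routes (abnormal count or >10% bands); both abnormal at once
# still count once.

#' SIRS criterion identifiers
#' @return Character vector of the four SIRS criterion ids.
#' @export
sirs_criteria <- function() {
  c("SIRS_TEMP", "SIRS_HR", "SIRS_RR", "SIRS_WBC")
}

#' Shock criterion identifiers
#' @return Character vector of the two shock criterion ids.
#' @export
shock_criteria <- function() {
  c("SHOCK_SBP", "SHOCK_LACTATE")
}

#' Evaluate observations against the individual alert criteria
#'
#' Maps each observation to the criterion it satisfies, or `NA` if it is
#' within normal limits. Boundaries are inclusive exactly as the rule is
#' stated (temperature at 36.0 or 38.0 degC qualifies, heart rate at 90,
#' respiratory rate at 20, WBC at 4,000 or 12,000, SBP at 90, lactate at
#' 2.0) except bands, which must strictly exceed the threshold.
#' Non-physiologic extremes still evaluate: the fielded system took
#' manually charted values at face value, and so does this one (see
#' [qc_flag_implausible()] for an optional plausibility screen).
#'
#' @param kind Character vector of observation kinds.
#' @param value Numeric values in canonical units (temperature in degC).
#' @param cfg A [criteria_config()].
#' @return Character vector: the satisfied criterion id per observation,
#'   `NA` where none is satisfied.
#' @export
#' @examples
#' cfg <- criteria_config()
#' evaluate_criterion("TEMPERATURE", 38.0, cfg)  # "SIRS_TEMP"
#' evaluate_criterion("HEART_RATE", 89, cfg)     # NA
evaluate_criterion <- function(kind, value, cfg = criteria_config()) {
  kind <- as.character(kind)
  unknown <- !kind %in% observation_kinds()
  if (any(unknown)) {
    stop("unsupported observation kind: ",
         paste(unique(kind[unknown]), collapse = ", "))
  }
  out <- rep(NA_character_, length(kind))
  out[kind == "TEMPERATURE" &
        (value <= cfg$temp_low | value >= cfg$temp_high)] <- "SIRS_TEMP"
  out[kind == "HEART_RATE" & value >= cfg$hr_min] <- "SIRS_HR"
  out[kind == "RESPIRATORY_RATE" & value >= cfg$rr_min] <- "SIRS_RR"
  out[kind == "WBC_COUNT" &
        (value <= cfg$wbc_low | value >= cfg$wbc_high)] <- "SIRS_WBC"
  out[kind == "BANDS_PERCENT" & value > cfg$bands_min_pct] <- "SIRS_WBC"
  out[kind == "SYSTOLIC_BP" & value <= cfg$sbp_max] <- "SHOCK_SBP"
  out[kind == "LACTATE" & value >= cfg$lactate_min] <- "SHOCK_LACTATE"
  out
}

#' Flag observations outside configurable physiologic plausibility ranges
#'
#' Optional quality-control screen. Values outside the plausible range are
#' flagged, never dropped: the screening rule itself evaluates every entry
#' as charted.
#'
#' @param obs Observation `data.frame` (see [observations()]).
#' @param ranges Named list of `c(low, high)` plausibility bounds per kind.
#' @return Logical vector, `TRUE` where the value is implausible.
#' @export
qc_flag_implausible <- function(obs, ranges = default_plausibility_ranges()) {
  flag <- rep(FALSE, nrow(obs))
  for (k in intersect(unique(obs$kind), names(ranges))) {
    i <- obs$kind == k
    r <- ranges[[k]]
    flag[i] <- obs$value[i] < r[1] | obs$value[i] > r[2]
  }
  flag
}

#' @rdname qc_flag_implausible
#' @export
default_plausibility_ranges <- function() {
  list(
    TEMPERATURE      = c(25, 45),
    HEART_RATE       = c(20, 300),
    RESPIRATORY_RATE = c(4, 80),
    SYSTOLIC_BP      = c(30, 300),
    WBC_COUNT        = c(100, 2e5),
    BANDS_PERCENT    = c(0, 100),
    LACTATE          = c(0, 30)
  )
}
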