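# Stateful per-encounter accumulation of satisfied criteria and alert
# emission. A criterion, once fulfilled by any observation, stays fulfilled
# for the remainder of the encounter: the engine assesses data elements
# asynchronously, so values from different time points combine.

empty_alerts <- function() {
  data.frame(encounter_id = character(), activation_time = as.POSIXct(character()),
             activation_index = integer(), satisfied_sirs = character(),
             satisfied_shock = character(), stringsAsFactors = FALSE)
}

#' Screen one encounter for sepsis alerts
#'
#' Consumes observations in time order; observations sharing a timestamp
#' are applied as one batch (vitals are charted as a set) and the alert
#' condition is checked once per batch. The first alert is emitted at the
#' timestamp whose batch first makes the condition true
#' (`sirs_required` SIRS criteria and `shock_required` shock signs
#' simultaneously fulfilled). A repeat alert is emitted whenever, with the
#' condition already true, a previously unfulfilled criterion becomes
#' fulfilled. With `repeat_on_reconfirmation = TRUE` a repeat also fires
#' when a batch re-confirms an already-fulfilled criterion, mimicking
#' production systems that re-activate on every qualifying entry.
#'
#' @param e An [encounter()].
#' @param cfg A [criteria_config()].
#' @param repeat_on_reconfirmation Logical; default `FALSE` (repeat only on
#'   strict growth of the satisfied-criteria set).
#' @return `data.frame` of alerts with columns `encounter_id`,
#'   `activation_time`, `activation_index`, `satisfied_sirs`,
#'   `satisfied_shock` (criterion ids, semicolon-joined); zero rows when
#'   the condition is never met.
#' @export
#' @examples
#' t0 <- as.POSIXct("2012-01-05 10:00:00", tz = "UTC")
#' e <- encounter("e1", observations(
#'   t0 + c(0, 1800, 3600),
#'   c("TEMPERATURE", "HEART_RATE", "LACTATE"),
#'   c(38.5, 95, 2.5)))
#' process_encounter(e)  # one alert, at the lactate result
process_encounter <- function(e, cfg = criteria_config(),
                              repeat_on_reconfirmation = FALSE) {
  obs <- e$observations
  if (nrow(obs) == 0) return(empty_alerts())
  crit <- evaluate_criterion(obs$kind, obs$value, cfg)

  # observations are sorted on construction, so same-timestamp batches are
  # runs of equal timestamps
  tnum <- as.numeric(obs$timestamp)
  batch <- cumsum(c(TRUE, tnum[-1] != tnum[-length(tnum)]))

  satisfied <- character()
  alerts <- list()
  active <- FALSE
  for (b in seq_len(batch[length(batch)])) {
    ts <- which(batch == b)
    batch_crit <- crit[ts][!is.na(crit[ts])]
    grew <- length(setdiff(batch_crit, satisfied)) > 0
    satisfied <- union(satisfied, batch_crit)
    n_sirs <- sum(satisfied %in% sirs_criteria())
    n_shock <- sum(satisfied %in% shock_criteria())
    condition <- n_sirs >= cfg$sirs_required && n_shock >= cfg$shock_required
    fire <- if (!active) {
      condition
    } else {
      condition && (grew || (repeat_on_reconfirmation && length(batch_crit) > 0))
    }
    if (fire) {
      alerts[[length(alerts) + 1L]] <- data.frame(
        encounter_id = e$encounter_id,
        activation_time = obs$timestamp[ts[1]],
        activation_index = length(alerts) + 1L,
        satisfied_sirs = paste(intersect(sirs_criteria(), satisfied), collapse = ";"),
        satisfied_shock = paste(intersect(shock_criteria(), satisfied), collapse = ";"),
        stringsAsFactors = FALSE)
      active <- TRUE
    }
  }
  if (length(alerts) == 0) return(empty_alerts())
  do.call(rbind, alerts)
}

#' Screen a collection of encounters
#'
#' @param encounters List of [encounter()] objects.
#' @inheritParams process_encounter
#' @param verbose Log one line per alert to `message()`.
#' @return Row-bound alert `data.frame` across all encounters.
#' @export
screen_encounters <- function(encounters, cfg = criteria_config(),
                              repeat_on_reconfirmation = FALSE,
                              verbose = FALSE) {
  out <- lapply(encounters, process_encounter, cfg = cfg,
                repeat_on_reconfirmation = repeat_on_reconfirmation)
  alerts <- do.call(rbind, c(out, list(empty_alerts())))
  rownames(alerts) <- NULL
  if (verbose && nrow(alerts) > 0) {
    apply(alerts, 1, function(a) message(sprintf(
      "INFO sepsis alert #%s encounter=%s time=%s criteria=%s;%s",
      a[["activation_index"]], a[["encounter_id"]], a[["activation_time"]],
      a[["satisfied_sirs"]], a[["satisfied_shock"]])))
  }
  alerts
}

#' Per-patient alert-count summary
#'
#' Tabulates alerts per encounter and summarises the distribution over
#' encounters that alerted at least once. Quartiles use Tukey's inclusive
#' hinge convention, which is deterministic on the small-integer counts
#' this produces.
#'
#' @param encounters List of [encounter()] objects.
#' @inheritParams process_encounter
#' @return List with `n_encounters`, `n_alerted`, `total_alerts`,
#'   `median`, `q1`, `q3`, `max` (`median`/quartiles `NA` when nothing
#'   alerted), and `per_encounter` (named integer vector of counts for the
#'   alerted encounters).
#' @export
alert_counts <- function(encounters, cfg = criteria_config(),
                         repeat_on_reconfirmation = FALSE) {
  alerts <- screen_encounters(encounters, cfg,
                              repeat_on_reconfirmation = repeat_on_reconfirmation)
  tab <- table(alerts$encounter_id)
  counts <- stats::setNames(as.integer(tab), names(tab))
  if (length(counts) == 0) {
    return(list(n_encounters = length(encounters), n_alerted = 0L,
                total_alerts = 0L, median = NA_real_, q1 = NA_real_,
                q3 = NA_real_, max = NA_integer_,
                per_encounter = integer()))
  }
  h <- stats::fivenum(unname(counts))
  list(n_encounters = length(encounters), n_alerted = length(counts),
       total_alerts = sum(counts), median = h[3], q1 = h[2], q3 = h[4],
       max = max(counts), per_encounter = counts)
}
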