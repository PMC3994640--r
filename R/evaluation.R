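# Diagnostic-accuracy analysis of alerts against chart-review labels.
#
# The verification design matters: when every alert-positive is adjudicated
# but only a random sample of negatives is, PPV and a sample-based NPV are
# estimable while sensitivity, specificity and AUROC are not. The report
# object carries that design and refuses to emit the non-estimable metrics.

#' Round half-up on the percent scale
#'
#' Display rounding used in all printed tables: half-way cases round away
#' from zero (38.05 -> 38.1), unlike [round()]'s round-half-even.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' 2x2 confusion counts for alerts against chart-review labels
#'
#' @param alerted Character vector of encounter ids that fired at least one
#'   alert.
#' @param labels Label `data.frame` with at least `encounter_id` and
#'   logical `sepsis` columns (see [read_labels()]). Under a
#'   sampled-negatives design the labelled non-alerts are only the reviewed
#'   sample, so `fn`/`tn` are within-sample counts.
#' @return List with integer `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(alerted, labels) {
  alerted <- unique(as.character(alerted))
  missing <- setdiff(alerted, labels$encounter_id)
  if (length(missing) > 0) {
    stop("no chart-review label for alerted encounter(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  is_alert <- labels$encounter_id %in% alerted
  list(tp = sum(is_alert & labels$sepsis),
       fp = sum(is_alert & !labels$sepsis),
       fn = sum(!is_alert & labels$sepsis),
       tn = sum(!is_alert & !labels$sepsis))
}

#' Exact (Clopper-Pearson) binomial proportion confidence interval
#'
#' Point estimate `successes/trials` with the exact interval obtained by
#' inverting binomial tail probabilities, computed through the
#' beta-quantile representation. At the boundaries the interval is
#' one-sided: lower bound 0 at zero successes, upper bound 1 at
#' `successes = trials` (where the lower bound is
#' \eqn{(\alpha/2)^{1/n}}).
#'
#' @param successes,trials Non-negative counts, `successes <= trials`,
#'   `trials >= 1`.
#' @param level Coverage probability (default 0.95).
#' @return Named numeric vector `c(point, lower, upper)`.
#' @export
#' @examples
#' proportion_ci(355, 795)  # 0.447 (0.412, 0.482)
proportion_ci <- function(successes, trials, level = 0.95) {
  stopifnot(length(successes) == 1, length(trials) == 1)
  if (trials < 1) stop("trials must be >= 1")
  if (successes < 0 || successes > trials) {
    stop("successes must lie in [0, trials]")
  }
  a <- 1 - level
  lower <- if (successes == 0) 0 else stats::qbeta(a / 2, successes, trials - successes + 1)
  upper <- if (successes == trials) 1 else stats::qbeta(1 - a / 2, successes + 1, trials - successes)
  c(point = successes / trials, lower = lower, upper = upper)
}

#' Cohen's kappa for paired ratings
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e) / (1 - p_e)} between
#' two raters over the same subjects. Works for any shared category set.
#' When both raters use a single identical category throughout
#' (\eqn{p_e = p_o = 1}) the statistic is defined as 1, the
#' full-agreement convention.
#'
#' @param a,b Equal-length rating vectors.
#' @return Kappa statistic in \[-1, 1\].
#' @export
cohen_kappa <- function(a, b) {
  if (length(a) != length(b)) stop("rating vectors differ in length")
  if (length(a) == 0) stop("ratings are empty")
  lev <- sort(unique(c(a, b)))
  fa <- factor(a, levels = lev)
  fb <- factor(b, levels = lev)
  n <- length(a)
  p_o <- mean(fa == fb)
  p_e <- sum((table(fa) / n) * (table(fb) / n))
  if (p_e >= 1) return(if (p_o >= 1) 1 else NaN)
  (p_o - p_e) / (1 - p_e)
}

# Subset labels to one evaluation group.
group_subset <- function(labels, alerted, group) {
  is_alert <- labels$encounter_id %in% alerted
  switch(group,
    TRUE_POSITIVE  = labels[is_alert & labels$sepsis, , drop = FALSE],
    FALSE_POSITIVE = labels[is_alert & !labels$sepsis, , drop = FALSE],
    TRUE_NEGATIVE  = labels[!is_alert & !labels$sepsis, , drop = FALSE],
    stop("unknown group: ", group)
  )
}

split_categories <- function(x) {
  unlist(strsplit(x[!is.na(x) & nzchar(x)], ";", fixed = TRUE))
}

#' Per-category counts and percentages within one evaluation group
#'
#' True positives are tabulated by infection category; false positives and
#' sampled true negatives by medical-condition category. Patients may carry
#' several categories, so percentages (of the group denominator) may sum
#' above 100.
#'
#' @param labels Label `data.frame` (see [read_labels()]).
#' @param alerted Character vector of alerted encounter ids.
#' @param group One of `"TRUE_POSITIVE"`, `"FALSE_POSITIVE"`,
#'   `"TRUE_NEGATIVE"`.
#' @return `data.frame` with `category`, `n`, `pct` (percent of the group,
#'   rounded half-up to one decimal), sorted by descending count.
#' @export
category_table <- function(labels, alerted, group = c("TRUE_POSITIVE",
                                                      "FALSE_POSITIVE",
                                                      "TRUE_NEGATIVE")) {
  group <- match.arg(group)
  sub <- group_subset(labels, alerted, group)
  if (nrow(sub) == 0) stop("group ", group, " is empty")
  col <- if (group == "TRUE_POSITIVE") "infection_categories" else "condition_categories"
  cats <- split_categories(sub[[col]])
  tab <- sort(table(cats), decreasing = TRUE)
  data.frame(category = names(tab), n = as.integer(tab),
             pct = round_half_up(100 * as.integer(tab) / nrow(sub), 1),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Disposition by evaluation group
#'
#' Cross-tabulates ED disposition (admitted / died in ED / discharged,
#' mutually exclusive) against true-positive, false-positive, and sampled
#' non-alert groups. Each group column's percentages sum to 100.
#'
#' @inheritParams category_table
#' @return `data.frame` with one row per disposition and, per group,
#'   `<group>_n` and `<group>_pct` columns.
#' @export
disposition_table <- function(labels, alerted) {
  dispositions <- c("ADMITTED", "DIED_IN_ED", "DISCHARGED")
  groups <- c(TRUE_POSITIVE = "tp", FALSE_POSITIVE = "fp",
              TRUE_NEGATIVE = "nonalert")
  out <- data.frame(disposition = dispositions, stringsAsFactors = FALSE)
  for (g in names(groups)) {
    sub <- group_subset(labels, alerted, g)
    n <- vapply(dispositions, function(d) sum(sub$disposition == d, na.rm = TRUE), 0L)
    out[[paste0(groups[[g]], "_n")]] <- as.integer(n)
    out[[paste0(groups[[g]], "_pct")]] <-
      if (nrow(sub) > 0) round_half_up(100 * n / nrow(sub), 1) else rep(NA_real_, 3)
  }
  out
}

#' Full diagnostic-accuracy report for a screening run
#'
#' Assembles the 2x2 counts, PPV, estimated NPV (both with exact intervals),
#' category tables and disposition table. Under the sampled-negatives
#' design (`negatives_sampled = TRUE`, the default) sensitivity,
#' specificity and AUROC are recorded as non-estimable and [metric_value()]
#' refuses to return them: only a random sample of non-alerts was
#' adjudicated, so the full-population negative margin is unknown.
#'
#' @param alerted Character vector of alerted encounter ids.
#' @param labels Label `data.frame` (see [read_labels()]).
#' @param negatives_sampled Logical: were non-alerts only sampled for
#'   review (`SAMPLED_NEGATIVES` design) rather than fully adjudicated?
#' @param level Confidence level for the intervals.
#' @return Object of class `accuracy_report`.
#' @export
accuracy_report <- function(alerted, labels, negatives_sampled = TRUE,
                            level = 0.95) {
  cc <- confusion_counts(alerted, labels)
  n_pos <- cc$tp + cc$fp
  n_neg <- cc$fn + cc$tn
  ppv <- if (n_pos > 0) proportion_ci(cc$tp, n_pos, level) else
    c(point = NA_real_, lower = NA_real_, upper = NA_real_)
  npv <- if (n_neg > 0) proportion_ci(cc$tn, n_neg, level) else
    c(point = NA_real_, lower = NA_real_, upper = NA_real_)
  design <- if (negatives_sampled) "SAMPLED_NEGATIVES" else "FULL_VERIFICATION"
  estimable <- c("ppv", "npv_estimated")
  non_estimable <- character()
  if (negatives_sampled) {
    non_estimable <- c("sensitivity", "specificity", "auroc")
  } else {
    estimable <- c(estimable, "sensitivity", "specificity")
  }
  tables <- list()
  for (g in c("TRUE_POSITIVE", "FALSE_POSITIVE", "TRUE_NEGATIVE")) {
    tables[[g]] <- tryCatch(category_table(labels, alerted, g),
                            error = function(e) NULL)
  }
  r <- list(tp = cc$tp, fp = cc$fp, fn_in_sample = cc$fn, tn_in_sample = cc$tn,
            ppv = ppv, npv_estimated = npv, level = level, design = design,
            estimable_metrics = estimable, non_estimable_metrics = non_estimable,
            category_tables = tables,
            disposition = disposition_table(labels, alerted))
  class(r) <- "accuracy_report"
  r
}

#' Extract a named metric from an accuracy report
#'
#' @param report An [accuracy_report()].
#' @param metric Metric name, e.g. `"ppv"`. Requesting a metric the study
#'   design cannot estimate (sensitivity, specificity or AUROC under
#'   sampled negatives) is an error, not an `NA`.
#' @return Named numeric `c(point, lower, upper)` for interval metrics.
#' @export
metric_value <- function(report, metric) {
  if (metric %in% report$non_estimable_metrics) {
    stop(metric, " is not estimable under the ", report$design,
         " design: non-alerts were only sampled for review")
  }
  switch(metric,
         ppv = report$ppv,
         npv_estimated = report$npv_estimated,
         sensitivity = proportion_ci(report$tp, report$tp + report$fn_in_sample,
                                     report$level),
         specificity = proportion_ci(report$tn_in_sample,
                                     report$tn_in_sample + report$fp,
                                     report$level),
         stop("unknown metric: ", metric))
}

#' @export
print.accuracy_report <- function(x, ...) {
  pct <- function(v) sprintf("%.1f%%", round_half_up(100 * v, 1))
  cat("Sepsis alert diagnostic accuracy (", x$design, " design)\n", sep = "")
  cat("\nAlerts vs chart-review sepsis\n")
  m <- matrix(c(x$tp, x$fp, x$tp + x$fp,
                x$fn_in_sample, x$tn_in_sample, x$fn_in_sample + x$tn_in_sample),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("Alert yes", "Alert no (sampled)"),
                              c("Sepsis", "No sepsis", "Total")))
  print(m)
  cat(sprintf("\nPPV %s (%.0f%% CI %s-%s)\n", pct(x$ppv[["point"]]),
              100 * x$level, pct(x$ppv[["lower"]]), pct(x$ppv[["upper"]])))
  cat(sprintf("Estimated NPV %s (%.0f%% CI %s-%s)\n",
              pct(x$npv_estimated[["point"]]), 100 * x$level,
              pct(x$npv_estimated[["lower"]]), pct(x$npv_estimated[["upper"]])))
  if (length(x$non_estimable_metrics) > 0) {
    cat("Not estimable under this design:",
        paste(x$non_estimable_metrics, collapse = ", "), "\n")
  }
  for (g in names(x$category_tables)) {
    tab <- x$category_tables[[g]]
    if (is.null(tab)) next
    cat("\n", g, " categories (n may overlap; multi-label)\n", sep = "")
    print(tab, row.names = FALSE)
  }
  cat("\nDisposition by group\n")
  print(x$disposition, row.names = FALSE)
  invisible(x)
}
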