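---
title: "Rule-based ED sepsis alerting: model, evaluation design, and synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based ED sepsis alerting: model, evaluation design, and synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edsepsis)
```

## The detection rule

`edsepsis` implements an emergency-department sepsis screen of the kind
run inside EMR systems: a *sepsis alert* fires for an encounter once at
least two SIRS (systemic inflammatory response syndrome) criteria **and**
at least one sign of shock have been fulfilled. The SIRS criteria are

1. temperature ≤ 36 °C or ≥ 38 °C,
2. respiratory rate ≥ 20 breaths/min,
3. heart rate ≥ 90 beats/min,
4. white-cell count ≤ 4,000 or ≥ 12,000 cells/mm³, **or** > 10% bands
   (one composite criterion with two satisfying routes);

the shock signs are systolic blood pressure ≤ 90 mm Hg or lactate ≥ 2.0.
All boundaries are inclusive except bands, which is strictly greater
than. Every threshold lives in `criteria_config()` and can be changed;
the defaults are the fielded rule. The rule is deliberately not
age-adjusted: `patient_age` is carried but never consulted.

Three modelling assumptions matter:

* **Asynchronous accumulation.** A criterion, once satisfied by any
  observation, stays satisfied for the rest of the encounter — there is
  no expiry window, so a fever at triage combines with a lactate result
  three hours later. This mirrors a real-time engine that assesses data
  elements asynchronously across the visit.
* **Batch evaluation at shared timestamps.** Vitals are charted as a
  set; observations sharing a timestamp are applied together and the
  condition is checked once per timestamp. This makes the alert count
  invariant to the order in which simultaneous entries were keyed in.
* **Repeat activation on strict growth.** After the first alert, a
  repeat alert is emitted when a *previously unfulfilled* criterion
  becomes fulfilled. Under this semantics an encounter can emit at most
  4 alerts with the default configuration (the first needs 3 criteria;
  3 more can accrue). Production systems have reported per-patient
  maxima above this, which suggests they also re-fired when an
  already-satisfied criterion was re-confirmed; that behaviour is
  available as `repeat_on_reconfirmation = TRUE` but is off by default,
  because a repeat that carries no new information is arguably an
  artefact of the implementation rather than of the patient.

```{r}
t0 <- as.POSIXct("2012-01-05 10:00:00", tz = "UTC")
e <- encounter("ex1", observations(
  t0 + c(0, 1800, 3600, 5400),
  c("TEMPERATURE", "HEART_RATE", "LACTATE", "RESPIRATORY_RATE"),
  c(38.5, 95, 2.5, 22)))
process_encounter(e)
```

## Units and degenerate inputs

Temperature is accepted in °C or °F and normalised to °C on ingestion
(°C = (°F − 32)·5/9); every other kind has one canonical unit. Lactate
is a deliberate special case: the rule's threshold of 2.0 is compared in
whatever unit the configuration is written in, and the unit string is
stored verbatim. Fielded descriptions of this rule print the threshold
as "mg/dL" although lactate is conventionally reported in mmol/L
(2.0 mmol/L ≈ 18 mg/dL); rather than guess which was meant, the package
treats the threshold as unit-agnostic and leaves conversion to the user.

Non-physiologic extremes (heart rate 400, temperature 45 °C) still
evaluate: screening systems driven by manually charted vitals take
entries at face value, and silently dropping them would hide exactly the
data-entry errors an auditor wants to see. `qc_flag_implausible()`
offers a separate, optional plausibility flag. Validation
(`validate_encounter()`) reports violations rather than raising, and is
idempotent.

## Evaluating the alerts

The evaluation reproduces a *sampled-negatives* verification design:
every alerted encounter is chart-reviewed, but only a random sample of
the (much more numerous) non-alerting encounters is. Under that design
PPV, and an NPV estimated within the reviewed sample, are the only
honest accuracy summaries — sensitivity, specificity and AUROC all need
the unreviewed negative margin. `accuracy_report()` therefore records
them as non-estimable and `metric_value()` refuses to return them; the
refusal is load-bearing and is asserted by the test suite.

Confidence intervals use the Clopper–Pearson exact method (beta-quantile
form). The choice is forced by the boundary: 300 of 300 sampled
non-alerts without sepsis gives an estimated NPV of 100% with exact
lower bound (α/2)^(1/300) ≈ 98.8%, which a normal-approximation interval
degenerates on. Display percentages round half-up to one decimal;
quartiles of per-patient alert counts use Tukey's inclusive hinges
(`fivenum`), which are deterministic on small integers.

Inter-rater agreement of the chart review is summarised by Cohen's
kappa, with the full-agreement degenerate case (`p_e = 1`) defined as 1.

The bundled `study_fixture()` reconstructs, row by row, the label table
of a three-month single-centre validation of this rule: 795 alerted
encounters (355 septic) plus 300 sampled non-alerts (none septic), with
infection/condition categories and dispositions laid out by a
deterministic cyclic block assignment so that every published marginal
count — and hence PPV 44.7% (95% CI 41.2–48.2%), estimated NPV 100.0%
(lower bound 98.8%), admission rates 91.0 / 83.0 / 5.7% and infection
shares 38.0% respiratory, 32.7% urinary — recomputes exactly from the
table. The rows themselves are synthetic: individual-level data were
never published. One caveat inherited from the source tables: their
printed grand-total row (293 / 802 / 1,095) is inconsistent with the
cells; the package always recomputes totals from cells, since the cells,
PPV and NPV are mutually consistent and the totals row is a
typographical artefact.

```{r}
fx <- study_fixture()
rep <- accuracy_report(fx$alerted, fx$labels)
metric_value(rep, "ppv")
```

## The synthetic cohort generator

`generate_cohort()` exists so the whole pipeline — ingestion, screening,
evaluation — can be exercised end-to-end with no patient data. It is
constructive, not merely distributional:

* **Alert-target encounters** start as normal trajectories
  (piecewise-constant vitals at 30-minute charting intervals over a
  2–12 h stay, one mid-stay lab draw; values truncated strictly inside
  normal limits) into which the required criteria are injected:
  `sirs_required` SIRS plus `shock_required` shock values by an anchor
  time, then `K ~ min(Poisson(extra_criteria_rate), remaining)`
  additional criteria at strictly later, distinct timestamps — so under
  strict-growth semantics the encounter emits exactly `1 + K` alerts.
  Abnormal values are drawn uniformly inside the abnormal region with a
  one-resolution margin off the threshold, exercising the boundaries
  without claiming clinical realism.
* **Non-alert encounters** may carry a single SIRS criterion (infected
  but not septic, mirroring the observed non-alert mix) or an isolated
  shock sign, and are then run through the alert engine itself; any that
  alert are redrawn. Label purity is guaranteed by the engine, not by an
  argument about the value distributions.

Calibration constants are fixed once: `ppv_target = 0.447` labels each
alerting encounter septic with that probability;
`extra_criteria_rate = 0.8` was chosen so the per-patient alert count
has median 2 and IQR [1, 2], matching the reported distribution. That
rate gives a mean of ≈ 1.8 alerts per alerted patient, somewhat above
the reported mean of 1.54 (1,224 alerts / 795 patients) — the median and
IQR are the calibration targets, and a lower rate would push the median
toward 1. Category mixes are treated as independent per-category
Bernoulli draws (patients may carry several categories, so published
shares sum past 100%; the true joint distribution is unknowable from
marginals), and dispositions are drawn per group from the observed
shares. Everything is deterministic given `seed`.

What passing tests on this cohort do **not** show: the generator's
trajectories are not physiologic (no autocorrelation beyond piecewise
constancy, no treatment response, no missingness patterns, no delayed or
erroneous manual charting), so recovering PPV ≈ 0.447 on synthetic data
validates the *pipeline arithmetic*, not the clinical operating
characteristics of the rule on any real population.

```{r}
co <- generate_cohort(cohort_spec(n_alert_target = 60, n_nonalert = 20, seed = 8))
counts <- vapply(co$encounters, function(e) nrow(process_encounter(e)), 0L)
table(alerts = counts[1:60])
sum(counts[61:80])  # non-alert encounters never fire
```

## Numerical and testing choices

The test suite checks the alert engine against a brute-force oracle that
recomputes the satisfied-criteria set from scratch for every prefix of
the stream (10,000 random streams of up to 12 observations, with
timestamp ties to exercise batching), verifies every threshold at, just
inside and just outside its boundary, checks the Clopper–Pearson
implementation against a bisection of the binomial tail CDF and verifies
its coverage ≥ 0.95 by exact enumeration over n = 5–50,
p = 0.05–0.95, and runs the default 795 + 300 synthetic cohort through
the full pipeline. These problem sizes keep the suite comfortably inside
a minute or two on one core while still hitting every branch the engine
has.

## Limitations

* The engine screens single ED encounters; cross-encounter continuation
  (sepsis developing later in hospital) is out of scope.
* Lactate unit semantics are configured, not inferred (see above).
* The sampled-negatives design caps what any evaluation on such data can
  claim: no sensitivity, specificity or ROC, and the NPV is an estimate
  within the reviewed sample, not a population statement.
* Pediatric SIRS variants, qSOFA/NEWS-type scores, and alert delivery to
  clinicians are deliberately not modelled.
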