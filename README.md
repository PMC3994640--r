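# edsepsis

Rule-based sepsis screening for the emergency department, with the
diagnostic-accuracy evaluation such a screen needs and a synthetic ED
cohort generator so everything is testable without patient data.

Sepsis is easy to treat early and hard to notice early: the syndrome is a
constellation of vital-sign and laboratory abnormalities that no single
clinician reliably assembles at the bedside. EMR-embedded screens
automate the assembly. `edsepsis` is for informaticians and
methodologists who build or audit such screens: it implements the
detection rule, evaluates its alerts against chart review, and makes the
statistical limits of the usual verification design explicit.

## The rule

A **sepsis alert** fires for an encounter once **≥ 2 SIRS criteria** and
**≥ 1 sign of shock** have been fulfilled, at any time points within the
visit (criteria accumulate asynchronously and never expire):

| SIRS criteria | Shock signs |
|---|---|
| T ≤ 36 °C or ≥ 38 °C | SBP ≤ 90 mm Hg |
| RR ≥ 20 /min | lactate ≥ 2.0 |
| HR ≥ 90 /min | |
| WBC ≤ 4,000 or ≥ 12,000 /mm³, or > 10% bands | |

All boundaries inclusive except bands (strict). Each fulfilment of an
*additional* criterion re-activates the alert. Thresholds are
configurable via `criteria_config()`.

Evaluation assumes the **sampled-negatives design**: all alerted
encounters chart-reviewed, only a random sample of non-alerts. PPV and a
within-sample NPV are computed with exact Clopper–Pearson intervals;
sensitivity, specificity and AUROC are reported as *non-estimable* — the
package refuses to print them rather than print nonsense.

## Worked example

```r
library(edsepsis)

t0 <- as.POSIXct("2012-01-05 10:00:00", tz = "UTC")
e <- encounter("ex1", observations(
  t0 + c(0, 1800, 3600, 5400),
  c("TEMPERATURE", "HEART_RATE", "LACTATE", "RESPIRATORY_RATE"),
  c(38.5, 95, 2.5, 22)))
process_encounter(e)
#>   encounter_id     activation_time activation_index            satisfied_sirs
#> 1          ex1 2012-01-05 11:00:00                1         SIRS_TEMP;SIRS_HR
#> 2          ex1 2012-01-05 11:30:00                2 SIRS_TEMP;SIRS_HR;SIRS_RR
#>   satisfied_shock
#> 1   SHOCK_LACTATE
#> 2   SHOCK_LACTATE
```

The fever (10:00) and tachycardia (10:30) are two SIRS criteria; the
lactate of 2.5 at 11:00 adds the shock sign that completes the condition,
so the first alert is stamped 11:00. The tachypnea at 11:30 is a *new*
criterion, hence one repeat activation.

Evaluating the bundled study fixture — a label table reconstructing,
marginal by marginal, a published three-month single-centre validation of
this rule (795 alerts, 355 with confirmed sepsis; 300 sampled non-alerts,
none septic):

```r
fx <- study_fixture()
rep <- accuracy_report(fx$alerted, fx$labels)
metric_value(rep, "ppv")
#>     point     lower     upper
#> 0.4465409 0.4116082 0.4818714
```

i.e. PPV 44.7% (95% CI 41.2–48.2%); `print(rep)` renders the full 2×2
table, estimated NPV 100.0% (lower bound 98.8%), infection/condition
category tables and dispositions, and lists
`sensitivity, specificity, auroc` as not estimable under this design.

A command-line surface wraps the same functions
(`inst/cli/edsepsis.R`, subcommands `screen`, `evaluate`, `simulate`,
`validate`), and `generate_cohort()` produces seeded synthetic cohorts
whose alert-target encounters all alert and whose non-alert encounters
provably never do.

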