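cfg <- criteria_config()
t0 <- as.POSIXct("2012-01-05 10:00:00", tz = "UTC")

mk <- function(id, kinds, values, offsets = seq_along(kinds) * 1800) {
  encounter(id, observations(t0 + offsets, kinds, values))
}

test_that("criteria from different time points combine to a single alert", {
  e <- mk("e1", c("TEMPERATURE", "HEART_RATE", "LACTATE"), c(38.5, 95, 2.5))
  a <- process_encounter(e, cfg)
  expect_identical(nrow(a), 1L)
  expect_identical(a$activation_time, t0 + 3 * 1800)  # at the completing datum
  expect_setequal(strsplit(a$satisfied_sirs, ";")[[1]], c("SIRS_TEMP", "SIRS_HR"))
  expect_identical(a$satisfied_shock, "SHOCK_LACTATE")
})

test_that("one SIRS criterion plus shock never alerts", {
  e <- mk("e2", c("TEMPERATURE", "LACTATE"), c(38.5, 2.5))
  expect_identical(nrow(process_encounter(e, cfg)), 0L)
})

test_that("fulfilment of an additional criterion repeats the alert", {
  e <- mk("e3", c("TEMPERATURE", "HEART_RATE", "LACTATE", "RESPIRATORY_RATE"),
          c(38.5, 95, 2.5, 22))
  a <- process_encounter(e, cfg)
  expect_identical(nrow(a), 2L)
  expect_identical(a$activation_index, 1:2)
  expect_identical(a$activation_time[2], t0 + 4 * 1800)
  expect_match(a$satisfied_sirs[2], "SIRS_RR")
})

test_that("re-confirming an already-satisfied criterion does not repeat by default", {
  e <- mk("e4", c("HEART_RATE", "HEART_RATE", "TEMPERATURE", "SYSTOLIC_BP",
                  "HEART_RATE"),
          c(95, 96, 38.5, 88, 97))
  a <- process_encounter(e, cfg)
  expect_identical(nrow(a), 1L)
  expect_identical(a$activation_time, t0 + 4 * 1800)
  # the production-style switch re-fires on the reconfirmation at t5
  a2 <- process_encounter(e, cfg, repeat_on_reconfirmation = TRUE)
  expect_identical(nrow(a2), 2L)
  expect_identical(a2$activation_time[2], t0 + 5 * 1800)
})

test_that("same-timestamp observations are applied as one batch, checked once", {
  e <- encounter("b1", observations(rep(t0, 3),
                                    c("TEMPERATURE", "HEART_RATE", "LACTATE"),
                                    c(38.5, 95, 2.5)))
  a <- process_encounter(e, cfg)
  expect_identical(nrow(a), 1L)
  expect_identical(a$activation_time, t0)
})

test_that("permuting observations within a shared timestamp leaves the alert count unchanged", {
  set.seed(42)
  for (rep_i in 1:20) {
    e <- random_stream_encounter("perm", max_n = 10)
    base <- nrow(process_encounter(e, cfg))
    obs <- e$observations
    perm <- obs[order(as.numeric(obs$timestamp), stats::runif(nrow(obs))), ]
    e2 <- encounter("perm", perm)
    expect_identical(nrow(process_encounter(e2, cfg)), base)
  }
})

test_that("appending observations never removes or re-times earlier alerts", {
  set.seed(7)
  for (rep_i in 1:50) {
    e <- random_stream_encounter("mono", max_n = 10)
    a1 <- process_encounter(e, cfg)
    extra <- observations(max(e$observations$timestamp) + c(600, 1200),
                          sample(observation_kinds(), 2, replace = TRUE),
                          c(stats::runif(1, 50, 140), stats::runif(1, 1, 4)))
    e2 <- encounter("mono", rbind(e$observations, extra))
    a2 <- process_encounter(e2, cfg)
    expect_gte(nrow(a2), nrow(a1))
    if (nrow(a1) > 0) {
      expect_equal(a2$activation_time[seq_len(nrow(a1))], a1$activation_time)
      expect_identical(a2$satisfied_sirs[seq_len(nrow(a1))], a1$satisfied_sirs)
    }
  }
})

test_that("strict-growth semantics cap alerts at 4 per encounter; 6 is unreachable", {
  # first alert needs >= 3 criteria (2 SIRS + 1 shock); each repeat needs a
  # new criterion; 6 criteria exist in total
  ceiling_alerts <- 6 - (cfg$sirs_required + cfg$shock_required) + 1
  expect_identical(ceiling_alerts, 4)
  # a stream fulfilling all six criteria one at a time achieves the ceiling
  e <- mk("max", c("TEMPERATURE", "HEART_RATE", "SYSTOLIC_BP",
                   "RESPIRATORY_RATE", "WBC_COUNT", "LACTATE"),
          c(38.5, 95, 88, 22, 13000, 2.5))
  expect_identical(nrow(process_encounter(e, cfg)), 4L)
  # no random stream exceeds it
  set.seed(11)
  most <- max(vapply(1:200, function(i) {
    nrow(process_encounter(random_stream_encounter("m", 12), cfg))
  }, 0L))
  expect_lte(most, 4L)
})

test_that("engine output equals brute-force prefix recomputation on random streams", {
  set.seed(101)
  for (i in 1:300) {
    expect_matches_oracle(random_stream_encounter(paste0("r", i)))
  }
})

test_that("alert counts summarise per alerted patient with Tukey quartiles", {
  enc <- list(
    mk("a", c("TEMPERATURE", "HEART_RATE", "LACTATE"), c(38.5, 95, 2.5)),
    mk("b", c("TEMPERATURE", "HEART_RATE", "LACTATE", "RESPIRATORY_RATE"),
       c(38.5, 95, 2.5, 22)),
    mk("c", c("TEMPERATURE", "HEART_RATE", "LACTATE", "WBC_COUNT"),
       c(38.5, 95, 2.5, 13000)),
    mk("d", "HEART_RATE", 95)  # never alerts
  )
  s <- alert_counts(enc, cfg)
  expect_identical(s$n_alerted, 3L)
  expect_identical(s$total_alerts, 5L)
  expect_identical(s$median, 2)
  expect_identical(s$max, 2L)

  empty <- alert_counts(list(mk("d", "HEART_RATE", 95)), cfg)
  expect_identical(empty$n_alerted, 0L)
  expect_identical(empty$total_alerts, 0L)
  expect_true(is.na(empty$median))
})
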