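test_that("confusion counts classify alerted vs sampled non-alert encounters", {
  labels <- data.frame(
    encounter_id = c("a", "b", "c"),
    sepsis = c(TRUE, TRUE, FALSE),
    infection_categories = c("urinary_tract", "bacteremia", ""),
    condition_categories = c("", "", "trauma"),
    disposition = c("ADMITTED", "ADMITTED", "DISCHARGED"),
    stringsAsFactors = FALSE)
  cc <- confusion_counts(c("a", "b"), labels)
  expect_identical(cc, list(tp = 2L, fp = 0L, fn = 0L, tn = 1L))
  expect_error(confusion_counts(c("a", "zzz"), labels), "zzz")
  empty <- confusion_counts(character(), labels[0, ])
  expect_identical(unlist(empty), c(tp = 0L, fp = 0L, fn = 0L, tn = 0L))
})

test_that("exact interval matches a binomial tail bisection oracle", {
  cases <- rbind(c(5, 10), c(1, 8), c(17, 23), c(355, 795), c(299, 300))
  for (i in seq_len(nrow(cases))) {
    x <- cases[i, 1]; n <- cases[i, 2]
    got <- proportion_ci(x, n)
    ora <- oracle_clopper_pearson(x, n)
    expect_equal(got[["lower"]], ora[["lower"]], tolerance = 1e-8)
    expect_equal(got[["upper"]], ora[["upper"]], tolerance = 1e-8)
    # second, independent cross-check
    bt <- stats::binom.test(x, n)$conf.int
    expect_equal(unname(got[c("lower", "upper")]), as.numeric(bt),
                 tolerance = 1e-12)
  }
})

test_that("interval boundaries are one-sided at 0 and n successes", {
  z <- proportion_ci(0, 10)
  expect_identical(z[["point"]], 0)
  expect_identical(z[["lower"]], 0)
  full <- proportion_ci(300, 300)
  expect_identical(full[["point"]], 1)
  expect_identical(full[["upper"]], 1)
  expect_equal(full[["lower"]], 0.025^(1 / 300), tolerance = 1e-12)
  expect_error(proportion_ci(1, 0), "trials")
  expect_error(proportion_ci(5, 3), "successes")
})

test_that("interval brackets the point and narrows with more trials", {
  for (n in c(10, 40, 160, 640)) {
    ci <- proportion_ci(round(0.3 * n), n)
    expect_lte(ci[["lower"]], ci[["point"]])
    expect_gte(ci[["upper"]], ci[["point"]])
  }
  widths <- vapply(c(10, 40, 160, 640), function(n) {
    ci <- proportion_ci(round(0.3 * n), n)
    ci[["upper"]] - ci[["lower"]]
  }, 0)
  expect_true(all(diff(widths) < 0))
})

test_that("kappa handles perfect, inverse and degenerate agreement", {
  expect_identical(cohen_kappa(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  expect_identical(cohen_kappa(c(1, 1, 0, 0), c(0, 0, 1, 1)), -1)
  expect_identical(cohen_kappa(rep(1, 5), rep(1, 5)), 1)  # p_e = p_o = 1
  expect_error(cohen_kappa(1:3, 1:4), "length")
})

test_that("kappa on a 30-record adjudication-style table is about 0.78", {
  # 2x2 contingency 18/1/2/9: observed agreement 27/30 = 0.9, chance
  # agreement (19*20 + 11*10)/900, kappa = (p_o - p_e)/(1 - p_e)
  a <- c(rep(1, 18), rep(1, 1), rep(0, 2), rep(0, 9))
  b <- c(rep(1, 18), rep(0, 1), rep(1, 2), rep(0, 9))
  p_o <- mean(a == b)
  p_e <- mean(a) * mean(b) + (1 - mean(a)) * (1 - mean(b))
  expect_equal(cohen_kappa(a, b), (p_o - p_e) / (1 - p_e), tolerance = 1e-12)
  expect_equal(round(cohen_kappa(a, b), 2), 0.78)
})

make_random_labels <- function(n_tp = 25, n_fp = 30, n_tn = 20) {
  n <- n_tp + n_fp + n_tn
  cats <- c("alpha", "beta", "gamma", "delta")
  draw <- function() paste(sample(cats, sample(1:3, 1)), collapse = ";")
  labels <- data.frame(
    encounter_id = sprintf("r%03d", seq_len(n)),
    sepsis = rep(c(TRUE, FALSE, FALSE), c(n_tp, n_fp, n_tn)),
    infection_categories = "", condition_categories = "",
    disposition = sample(c("ADMITTED", "DIED_IN_ED", "DISCHARGED"), n,
                         replace = TRUE),
    stringsAsFactors = FALSE)
  labels$infection_categories[labels$sepsis] <- replicate(n_tp, draw())
  labels$condition_categories[!labels$sepsis] <- replicate(n_fp + n_tn, draw())
  list(labels = labels, alerted = labels$encounter_id[seq_len(n_tp + n_fp)])
}

test_that("category table equals a brute-force membership recount", {
  set.seed(5)
  fx <- make_random_labels()
  for (g in c("TRUE_POSITIVE", "FALSE_POSITIVE", "TRUE_NEGATIVE")) {
    tab <- category_table(fx$labels, fx$alerted, g)
    col <- if (g == "TRUE_POSITIVE") "infection_categories" else "condition_categories"
    in_alert <- fx$labels$encounter_id %in% fx$alerted
    sub <- switch(g,
                  TRUE_POSITIVE = fx$labels[in_alert & fx$labels$sepsis, ],
                  FALSE_POSITIVE = fx$labels[in_alert & !fx$labels$sepsis, ],
                  TRUE_NEGATIVE = fx$labels[!in_alert & !fx$labels$sepsis, ])
    for (i in seq_len(nrow(tab))) {
      brute <- sum(vapply(strsplit(sub[[col]], ";"),
                          function(s) tab$category[i] %in% s, TRUE))
      expect_identical(tab$n[i], brute)
      expect_identical(tab$pct[i], round_half_up(100 * brute / nrow(sub), 1))
    }
  }
})

test_that("a patient with two categories counts once in each row", {
  labels <- data.frame(encounter_id = "solo", sepsis = TRUE,
                       infection_categories = "urinary_tract;bacteremia",
                       condition_categories = "", disposition = "ADMITTED",
                       stringsAsFactors = FALSE)
  tab <- category_table(labels, "solo", "TRUE_POSITIVE")
  expect_identical(sort(tab$category), c("bacteremia", "urinary_tract"))
  expect_identical(tab$n, c(1L, 1L))
  expect_identical(tab$pct, c(100, 100))
})

test_that("disposition columns are exclusive and sum to 100 percent", {
  set.seed(6)
  fx <- make_random_labels()
  tab <- disposition_table(fx$labels, fx$alerted)
  for (col in c("tp_pct", "fp_pct", "nonalert_pct")) {
    expect_equal(sum(tab[[col]]), 100, tolerance = 0.16)  # display rounding only
  }
  # recount one cell by brute force
  in_alert <- fx$labels$encounter_id %in% fx$alerted
  brute <- sum(fx$labels$disposition == "ADMITTED" & in_alert & fx$labels$sepsis)
  expect_identical(tab$tp_n[tab$disposition == "ADMITTED"], brute)
})

test_that("sampled-negatives reports refuse sensitivity, specificity and AUROC", {
  fx <- make_random_labels()
  rep_s <- accuracy_report(fx$alerted, fx$labels, negatives_sampled = TRUE)
  expect_identical(rep_s$design, "SAMPLED_NEGATIVES")
  expect_setequal(rep_s$non_estimable_metrics,
                  c("sensitivity", "specificity", "auroc"))
  expect_error(metric_value(rep_s, "sensitivity"), "not estimable")
  expect_error(metric_value(rep_s, "auroc"), "not estimable")
  expect_false(any(grepl("sensitivity\\s*[0-9]",
                         utils::capture.output(print(rep_s)))))
  # full verification estimates them
  rep_f <- accuracy_report(fx$alerted, fx$labels, negatives_sampled = FALSE)
  expect_identical(rep_f$design, "FULL_VERIFICATION")
  expect_equal(metric_value(rep_f, "sensitivity")[["point"]], 1)
})

test_that("half-up display rounding differs from round-half-even where it should", {
  expect_identical(round_half_up(38.05, 1), 38.1)
  expect_identical(round_half_up(0.25, 1), 0.3)
  expect_identical(round_half_up(-0.25, 1), -0.3)
})
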