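test_that("PRR, ROR and chi-squared reproduce hand computations", {
  flat <- contingency_2x2(10, 90, 10, 90)
  expect_equal(prr(flat), 1)
  expect_equal(chi2_2x2(flat, yates = FALSE), 0)
  r <- ror_with_ci(contingency_2x2(25, 25, 25, 25))
  expect_equal(r[["ror"]], 1)
  expect_equal(log(r[["ci_low"]]), -log(r[["ci_high"]]), tolerance = 1e-12)

  tab <- contingency_2x2(30, 70, 100, 900)
  expect_equal(prr(tab), 3)
  rr <- ror_with_ci(tab)
  expect_equal(rr[["ror"]], 27000 / 7000, tolerance = 1e-12)
  expect_equal(unname(rr[c("ci_low", "ci_high")]),
               oracle_ror_ci(30, 70, 100, 900), tolerance = 1e-12)
  expect_equal(chi2_2x2(tab, yates = FALSE), oracle_chi2(30, 70, 100, 900),
               tolerance = 1e-10)

  expect_equal(ror_with_ci(contingency_2x2(3, 1, 1, 3))[["ror"]], 9)
})

test_that("zero cells error unless the continuity correction is enabled", {
  z <- contingency_2x2(0, 100, 10, 890)
  expect_error(prr(z), "zero denominator|zero cell")
  expect_error(ror_with_ci(z), "zero cell")
  expect_equal(prr(z, correction = TRUE),
               (0.5 / 101) / (10.5 / 901), tolerance = 1e-12)
  expect_error(contingency_2x2(-1, 1, 1, 1), "nonnegative")
  expect_error(chi2_2x2(contingency_2x2(0, 0, 5, 5)), "zero margin")
})

test_that("Yates correction never exceeds the uncorrected statistic", {
  set.seed(7)
  for (i in 1:50) {
    cells <- rpois(4, lambda = c(20, 80, 60, 500)) + 1
    tab <- contingency_2x2(cells[1], cells[2], cells[3], cells[4])
    expect_lte(chi2_2x2(tab, yates = TRUE), chi2_2x2(tab, yates = FALSE) + 1e-12)
  }
})

test_that("estimators match brute-force oracles on 1,000 random tables", {
  set.seed(123)
  for (i in 1:1000) {
    cells <- rpois(4, lambda = sample(5:200, 4, replace = TRUE)) + 1
    a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
    tab <- contingency_2x2(a, b, c, d)
    expect_equal(prr(tab), oracle_prr(a, b, c, d), tolerance = 1e-10)
    expect_equal(ror_with_ci(tab)[["ror"]], oracle_ror(a, b, c, d),
                 tolerance = 1e-10)
    expect_equal(chi2_2x2(tab, yates = FALSE), oracle_chi2(a, b, c, d),
                 tolerance = 1e-10)
    expect_equal(chi2_2x2(tab, yates = TRUE),
                 oracle_chi2(a, b, c, d, yates = TRUE), tolerance = 1e-10)
  }
})

test_that("swapping drug rows inverts PRR and ROR", {
  set.seed(99)
  for (i in 1:50) {
    cells <- rpois(4, 50) + 1
    t1 <- contingency_2x2(cells[1], cells[2], cells[3], cells[4])
    t2 <- contingency_2x2(cells[3], cells[4], cells[1], cells[2])
    expect_equal(prr(t1) * prr(t2), 1, tolerance = 1e-10)
    expect_equal(ror_with_ci(t1)[["ror"]] * ror_with_ci(t2)[["ror"]], 1,
                 tolerance = 1e-10)
  }
})

test_that("the dual signal rule matches the printed thresholds", {
  # published urticaria row: both rules positive
  rule <- signal_rule(11.60, 2069.63, 223, 11.46)
  expect_true(rule$prr_positive)
  expect_true(rule$ror_positive)
  expect_true(rule$signal)

  # PRR exactly at the (strict) threshold is not positive; chi2 at 4 is
  expect_false(signal_rule(2, 100, 10, 2)$prr_positive)
  expect_true(signal_rule(2.01, 4, 10, 2)$prr_positive)
  # N below 3 blocks the ROR rule even with a strong interval
  r2 <- signal_rule(5, 10, 2, 3)
  expect_true(r2$prr_positive)
  expect_false(r2$ror_positive)
  expect_false(r2$signal)
  # CI lower limit exactly 1 is not positive (strict)
  expect_false(signal_rule(5, 10, 10, 1)$ror_positive)
})

test_that("flag_signal combines estimators and rule consistently", {
  res <- flag_signal(contingency_2x2(30, 70, 100, 900))
  expect_true(res$signal)
  expect_equal(res$prr, 3)
  res_null <- flag_signal(contingency_2x2(10, 90, 10, 90))
  expect_false(res_null$signal)
})

test_that("every published signal row passes the dual rule", {
  fx <- omalizumab_case_study()
  tab <- fx$signal_table
  rule <- signal_rule(tab$prr, tab$chi2, tab$n_case, tab$ror_ci_low)
  expect_true(all(rule$signal))
})

test_that("screen_events tabulates per-event 2x2 tables at report level", {
  reports <- data.frame(
    report_id = c("r1", "r1", "r2", "r3", "r4", "r5", "r6"),
    drug = c("OMZ", "OMZ", "OMZ", "omz ", "other", "other", "other"),
    event = c("rash", "rash", "rash", "rash", "rash", "fever", "fever"))
  out <- screen_events(reports, "OMZ")
  rash <- out[out$event == "rash", ]
  expect_equal(rash$a, 3)   # duplicate mention in r1 counted once
  expect_equal(rash$b, 0)
  expect_equal(rash$c, 1)
  expect_equal(rash$d, 2)

  # single-report dataset: nothing can reach N >= 3
  one <- data.frame(report_id = "r1", drug = "OMZ", event = "rash")
  expect_false(any(screen_events(one, "OMZ")$signal))

  expect_error(screen_events(data.frame(report_id = character(0),
                                        drug = character(0),
                                        event = character(0)), "OMZ"),
               "empty")
})

test_that("results are sorted by case count then PRR with name tie-breaks", {
  set.seed(5)
  reports <- simulate_reports(
    5000, c(e1 = 0.25, e2 = 0.25, e3 = 0.25, e4 = 0.25), 0.2,
    signal_lambda = c(e1 = 3), seed = 9)
  out <- screen_events(reports, "target_drug")
  expect_true(all(diff(out$a) <= 0))
})
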