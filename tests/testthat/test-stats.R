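test_that("odds ratio, log-SE, CI, z and p follow the log method", {
  # identity table: OR 1, CI symmetric about 1 on the log scale
  r <- odds_ratio(10, 10, 10, 10)
  expect_equal(r$odds_ratio, 1)
  expect_equal(r$log_se, sqrt(0.4))
  expect_equal(log(r$ci_low), -log(r$ci_high))
  expect_equal(r$p_two_tailed, 1)

  # hand evaluation of an asymmetric table
  h <- odds_ratio(12, 5, 7, 20)
  expect_equal(h$odds_ratio, (12 / 5) / (7 / 20))
  se <- sqrt(1 / 12 + 1 / 5 + 1 / 7 + 1 / 20)
  expect_equal(h$log_se, se)
  expect_equal(h$ci_low, exp(log(h$odds_ratio) - 1.96 * se), tolerance = 1e-4)
  expect_equal(h$z, log(h$odds_ratio) / se)
  expect_equal(h$p_two_tailed, 2 * pnorm(-abs(h$z)))
})

test_that("transposing exposure and control inverts the odds ratio", {
  set.seed(42)
  for (i in 1:20) {
    cells <- rpois(4, 50) + 1
    r1 <- odds_ratio(cells[1], cells[2], cells[3], cells[4])
    r2 <- odds_ratio(cells[3], cells[4], cells[1], cells[2])
    expect_equal(r1$odds_ratio * r2$odds_ratio, 1)
    expect_equal(r1$ci_low, 1 / r2$ci_high)
    expect_equal(r1$p_two_tailed, r2$p_two_tailed)
  }
})

test_that("a zero cell triggers the Haldane-Anscombe correction; empty margins error", {
  r <- odds_ratio(1, 10, 0, 10)
  # direct evaluation of the corrected formula
  expect_true(r$corrected)
  expect_equal(r$odds_ratio, (1.5 / 10.5) / (0.5 / 10.5))
  expect_equal(r$log_se, sqrt(1 / 1.5 + 1 / 10.5 + 1 / 0.5 + 1 / 10.5))
  expect_false(odds_ratio(5, 5, 5, 5)$corrected)

  expect_error(odds_ratio(0, 0, 3, 4), "empty")
  expect_error(odds_ratio(0, 3, 0, 4), "empty")
  expect_error(odds_ratio(-1, 3, 2, 4), "nonnegative")
})

test_that("interval coverage sits near the nominal 95% under binomial sampling", {
  cov <- ci_coverage_sim(true_or = 1.6, p_control = 0.05,
                         n_exposed = 4000, n_control = 4000,
                         n_rep = 300, seed = 5)
  expect_gt(cov$coverage, 0.91)
  expect_lt(cov$coverage, 0.99)
})

test_that("2x2 construction recounts the alert records, stratified and combined", {
  sim <- simulate_cohort(small_config(response_prob_pre = 0.2,
                                      response_prob_post = 0.4,
                                      baseline_visit_rate = 2))
  cfg <- sim$config
  al <- generate_alerts(build_timeline(sim$behavior),
                        period_start = cfg$period_start,
                        period_length_days = cfg$period_length_days)
  m <- match_alert_visits(al, sim$visits)
  comb <- build_two_by_two(al, m, "none")
  matched_ids <- m$alert_id
  # brute-force recount straight off the alert records
  expect_identical(comb$a, sum(al$period == 2 & al$alert_id %in% matched_ids))
  expect_identical(comb$b, sum(al$period == 2 & !al$alert_id %in% matched_ids))
  expect_identical(comb$c, sum(al$period == 1 & al$alert_id %in% matched_ids))
  expect_identical(comb$d, sum(al$period == 1 & !al$alert_id %in% matched_ids))

  for (strat in c("scratch_level", "lick_level")) {
    tb <- build_two_by_two(al, m, strat)
    lvl_col <- if (strat == "scratch_level") al$scratch_level_at_alert else al$lick_level_at_alert
    for (lv in 0:3) {
      row <- tb[stratum == level_labels()[as.character(lv)]]
      expect_identical(row$a, sum(al$period == 2 & lvl_col == lv &
                                    al$alert_id %in% matched_ids))
    }
    # stratum rows partition the combined table
    expect_identical(tb[stratum != "combined", sum(a + b)], comb$a + comb$b)
    expect_identical(tb[stratum != "combined", sum(c + d)], comb$c + comb$d)
    # combined row identical under either stratification
    expect_identical(tb[stratum == "combined", .(a, b, c, d)],
                     comb[, .(a, b, c, d)])
  }
})

test_that("percentages require a positive denominator", {
  expect_equal(pct(1, 8), 12.5)
  expect_equal(pct(0, 5), 0)
  expect_error(pct(1, 0), "positive")
})
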