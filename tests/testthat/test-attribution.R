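test_that("each alert pairs with the first qualifying visit, one-to-one", {
  al <- make_alerts("d1", 100)
  vi <- make_visits("d1", c(103, 110))
  m <- match_alert_visits(al, vi)
  expect_identical(nrow(m), 1L)
  expect_identical(m$visit_id, "v001")       # day 103, not 110
  expect_identical(m$lag_days, 3L)
  expect_identical(m$week_bin, 1L)

  # a visit at lag 29 is outside the 4-week window
  expect_identical(nrow(match_alert_visits(make_alerts("d1", 100),
                                           make_visits("d1", 129))), 0L)
  # visits before the alert are never alert visits
  expect_identical(nrow(match_alert_visits(make_alerts("d1", 100),
                                           make_visits("d1", 95))), 0L)
  # lag 0 (same-day visit) is within the window, week bin 1
  m0 <- match_alert_visits(make_alerts("d1", 100), make_visits("d1", 100))
  expect_identical(m0$lag_days, 0L)
  expect_identical(m0$week_bin, 1L)
  # day 28 is the last day in the window, week bin 4
  m28 <- match_alert_visits(make_alerts("d1", 100), make_visits("d1", 128))
  expect_identical(m28$lag_days, 28L)
  expect_identical(m28$week_bin, 4L)

  expect_error(match_alert_visits(al, vi, window_days = -1), "nonnegative")
})

test_that("a consumed visit cannot discharge a second alert", {
  al <- make_alerts("d1", c(100, 102))
  vi <- make_visits("d1", 104)
  m <- match_alert_visits(al, vi)
  expect_identical(nrow(m), 1L)
  expect_identical(m$alert_id, "a001")       # chronological greed
})

test_that("matching agrees with the quadratic brute-force matcher on cohorts", {
  for (seed in c(3, 17)) {
    cfg <- cohort_config(n_dogs = 25, period_length_days = 50, rng_seed = seed,
                         baseline_visit_rate = 3, response_prob_pre = 0.2,
                         response_prob_post = 0.4)
    sim <- simulate_cohort(cfg)
    al <- generate_alerts(build_timeline(sim$behavior),
                          period_start = cfg$period_start,
                          period_length_days = cfg$period_length_days)
    got <- match_alert_visits(al, sim$visits)
    want <- oracle_match(al, sim$visits)
    setkey(got, alert_id)
    want <- want[order(want$alert_id), ]
    expect_equal(got$alert_id, want$alert_id)
    expect_equal(got$visit_id, want$visit_id)
    expect_equal(got$lag_days, want$lag_days)
  }
})

test_that("matching conserves alerts and visits and is one-to-one", {
  sim <- simulate_cohort(small_config(baseline_visit_rate = 2.5,
                                      response_prob_pre = 0.15,
                                      response_prob_post = 0.3))
  al <- generate_alerts(build_timeline(sim$behavior),
                        period_start = sim$config$period_start,
                        period_length_days = sim$config$period_length_days)
  m <- match_alert_visits(al, sim$visits)
  expect_false(any(duplicated(m$alert_id)))
  expect_false(any(duplicated(m$visit_id)))
  expect_lte(nrow(m), min(nrow(al), nrow(sim$visits)))
  expect_true(all(m$alert_id %in% al$alert_id))
  expect_true(all(m$visit_id %in% sim$visits$visit_id))
  expect_true(all(m$lag_days >= 0 & m$lag_days <= 28))
  expect_equal(m$week_bin, as.integer(ceiling(pmax(m$lag_days, 1) / 7)))

  # shrinking the window never increases the number of matches
  sizes <- vapply(c(28, 21, 14, 7, 0),
                  function(w) nrow(match_alert_visits(al, sim$visits, w)),
                  integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("dermatitis subgroups follow the 0 / 1 / 2-5 / 6+ first-period rule", {
  vis <- rbind(make_visits("g2", c(10, 40, 70), derm = rep(TRUE, 3)),
               make_visits("g3", seq(10, 110, by = 20), derm = rep(TRUE, 6)),
               make_visits("g1", c(20, 30), derm = c(TRUE, FALSE)),
               make_visits("late", 300, derm = TRUE))  # outside period 1
  p1 <- as.Date("2019-01-02") + c(0, 291)
  sg <- assign_subgroups(vis, p1[1], p1[2],
                         dogs = c("g1", "g2", "g3", "late", "novisit"))
  got <- setNames(sg$group, sg$dog_id)
  expect_identical(got[["g2"]], 2L)
  expect_identical(got[["g3"]], 3L)
  expect_identical(got[["g1"]], 1L)
  expect_identical(got[["late"]], 0L)     # dermatitis visit in period 2 only
  expect_identical(got[["novisit"]], 0L)  # no visits at all
})

test_that("prescription flags depend only on the visit date", {
  al <- make_alerts("d1", 100)
  vi <- rbind(make_visits("d1", 110), make_visits("d1", 160))
  vi$visit_id <- c("vA", "vB")
  rx <- data.frame(prescription_id = c("r1", "r2", "r3"),
                   visit_id = c("vA", "vA", "vB"),
                   drug_name = c("oclacitinib", "amoxicillin", "benzoyl peroxide"))
  out <- attribute_prescriptions(rx, vi, al)
  expect_identical(out$within_4wk_of_alert, c(TRUE, TRUE, FALSE))

  orphan <- rbind(rx, data.frame(prescription_id = "r4", visit_id = "vZ",
                                 drug_name = "prednisone"))
  expect_error(attribute_prescriptions(orphan, vi, al), "unknown visit")
})

test_that("week binning conserves matches and counts leftovers", {
  m <- data.frame(alert_id = sprintf("a%d", 1:4), visit_id = sprintf("v%d", 1:4),
                  dog_id = "d1", lag_days = c(3L, 9L, 20L, 27L),
                  week_bin = c(1L, 2L, 3L, 4L))
  wb <- bin_matches_by_week(m, total_visits = 10)
  expect_equal(unlist(wb[, c("week1", "week2", "week3", "week4")],
                      use.names = FALSE), rep(1L, 4))
  expect_identical(wb$matched, 4L)
  expect_identical(wb$outside_window, 6L)

  empty <- bin_matches_by_week(m[0, ])
  expect_identical(empty$matched, 0L)
})
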