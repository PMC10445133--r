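alerts_for <- function(behavior, ...) {
  generate_alerts(build_timeline(behavior), ...)
}

test_that("a one-level rise in the rolling mean triggers a single scratch alert", {
  # constant 40 s/day, stepping to 100 from day 12: the 7-day mean crosses
  # the 53 s/day cut on day 13
  b <- make_behavior("d1", c(rep(40, 11), rep(100, 19)))
  al <- alerts_for(b, period_start = as.Date("2019-01-02"))
  expect_identical(nrow(al), 1L)
  expect_identical(al$trigger, "scratch")
  expect_equal(al$date, as.Date("2019-01-02") + 12)  # day 13
  expect_identical(al$scratch_level_at_alert, 1L)
  expect_identical(al$lick_level_at_alert, 0L)
})

test_that("no alert can fire before day 9 of usage", {
  # a single spike lifts the rolling mean over the 53 s/day cut exactly on
  # day 8 of usage, after which the level plateaus at occasional
  b <- make_behavior("d1", c(rep(50, 7), 80, rep(60, 22)))
  tl <- build_timeline(b)
  d8 <- as.Date("2019-01-02") + 7
  expect_identical(tl[date == d8, scratch_level], 1L)          # the level rose...
  expect_identical(tl[date == d8 - 1, scratch_level], 0L)
  expect_identical(nrow(generate_alerts(tl)), 0L)              # ...but day 8 is mute
  # the identical timeline alerts once the usage-day floor admits day 8
  early <- generate_alerts(tl, min_usage_day = 8)
  expect_identical(nrow(early), 1L)
  expect_equal(early$date, d8)
})

test_that("constant behaviour and level decreases never alert", {
  expect_identical(nrow(alerts_for(make_behavior("d1", rep(80, 40)))), 0L)
  # step down: occasional -> infrequent
  b <- make_behavior("d1", c(rep(80, 15), rep(10, 25)))
  expect_identical(nrow(alerts_for(b)), 0L)
})

test_that("simultaneous scratch and lick rises collapse to one 'both' alert", {
  b <- make_behavior("d1",
                     scratch = c(rep(40, 11), rep(200, 19)),
                     lick = c(rep(4, 11), rep(30, 19)))
  al <- alerts_for(b)
  expect_true(all(al[, .N, by = date]$N == 1L))
  expect_true("both" %in% al$trigger)
})

test_that("alert generation matches the brute-force day-by-day oracle", {
  for (seed in c(1, 7, 99)) {
    cfg <- cohort_config(n_dogs = 40, period_length_days = 30, rng_seed = seed,
                         wear_prob = 0.8, partial_wear_fraction_range = c(0, 0.9))
    sim <- simulate_cohort(cfg)
    got <- generate_alerts(build_timeline(sim$behavior),
                           period_start = cfg$period_start,
                           period_length_days = cfg$period_length_days)
    want <- oracle_alerts(sim$behavior)
    expect_identical(nrow(got), nrow(want))
    if (nrow(want)) {
      setkey(got, dog_id, date)
      want <- want[order(want$dog_id, want$date), ]
      expect_equal(got$dog_id, want$dog_id)
      expect_equal(got$date, want$date)
      expect_equal(got$trigger, want$trigger)
      expect_equal(got$scratch_level_at_alert, want$scratch_level_at_alert)
      expect_equal(got$lick_level_at_alert, want$lick_level_at_alert)
    }
  }
})

test_that("alert summaries recount the emitted alert records", {
  sim <- simulate_cohort(small_config())
  al <- generate_alerts(build_timeline(sim$behavior),
                        period_start = sim$config$period_start,
                        period_length_days = sim$config$period_length_days)
  dogs <- sort(unique(al$dog_id))
  s <- summarize_alerts(al, dogs)
  counts <- table(factor(al$dog_id, levels = dogs))
  expect_identical(s$total_alerts, as.integer(nrow(al)))
  expect_equal(s$mean_per_dog, mean(counts))
  expect_equal(s$median_per_dog, median(as.integer(counts)))
  expect_equal(s$max_per_dog, max(counts))
  expect_equal(s$range, max(counts) - min(counts))

  one <- summarize_alerts(al[1], al$dog_id[1])
  expect_equal(one$mean_per_dog, 1)
  expect_equal(one$range, 0)
  expect_error(summarize_alerts(al, character(0)), "empty")
})

test_that("at most one alert per dog-day, order-invariant counts", {
  sim <- simulate_cohort(small_config(rng_seed = 7))
  tl <- build_timeline(sim$behavior)
  al <- generate_alerts(tl)
  expect_true(all(al[, .N, by = .(dog_id, date)]$N == 1L))
  # processing dogs in reversed order changes nothing
  rev_tl <- tl[order(-rank(dog_id), date)]
  al2 <- generate_alerts(rev_tl)
  expect_identical(nrow(al2), nrow(al))
  setkey(al2, dog_id, date)
  expect_equal(al2$date, al$date)
})
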