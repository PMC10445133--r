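#' Simulate a two-period activity-monitor cohort
#'
#' Generates daily scratch/lick telemetry, clinic visits and prescriptions
#' with the structure the downstream analysis assumes. Behaviour is a
#' right-skewed multiplicative process: each dog has log-normal baseline
#' means, days carry gamma-distributed noise, and Poisson-seeded pruritic
#' flares, clustered in time around a dog-specific itchy season
#' (`flare_cluster_sd`), multiply both behaviours by `flare_magnitude` for
#' `flare_duration_days`, with noisier day-to-day variation while the flare
#' waxes and wanes (`flare_noise_shape`). Collar wear is full with probability `wear_prob`,
#' otherwise a uniform partial fraction; recorded values on partial-wear days
#' are treated as daily-rate estimates (the telemetry normalises for wear
#' time), and no-wear days record exactly zero.
#'
#' Visits come from two processes: an alert-independent Poisson background
#' (`baseline_visit_rate` per dog per period, uniform dates), and an
#' owner-response process — for every alert that the alerting rules
#' themselves would emit on the generated telemetry, an extra visit is
#' scheduled with probability `response_prob_pre` (period 1) or
#' `response_prob_post` (period 2), at a lag drawn from a geometric
#' distribution (mean `response_lag_mean` days) truncated at 28 days, so
#' most owner responses arrive within the first week.
#' Same-day visits of one dog collapse into a single visit record.
#' Prescriptions are drawn per visit (Poisson counts, distinct drugs from
#' [drug_catalogue()]).
#'
#' The run is a pure function of `config`: identical configurations,
#' including `rng_seed`, reproduce identical tables. Raising
#' `response_prob_post` with everything else fixed reuses the same underlying
#' uniform draws, so the set of induced post-period visits only grows.
#'
#' @param config A [cohort_config()] object.
#' @param thresholds [level_thresholds()] used by the internal alert pass
#'   that drives the owner-response process.
#' @return A list of class `cohort_sim` with `data.table`s `behavior`
#'   (`dog_id`, `date`, `scratch_seconds`, `lick_minutes`, `wear_fraction`),
#'   `visits` (`visit_id`, `dog_id`, `date`, `dermatitis_outcome`),
#'   `prescriptions` (`prescription_id`, `visit_id`, `drug_name`,
#'   `category`), and the `config`.
#' @examples
#' sim <- simulate_cohort(cohort_config(n_dogs = 5, period_length_days = 30,
#'                                      rng_seed = 42))
#' nrow(sim$behavior)  # 5 dogs x 60 days
#' @export
simulate_cohort <- function(config, thresholds = level_thresholds()) {
  validate_config(config)
  span <- config$period_length_days * config$n_periods
  n <- config$n_dogs
  dates <- config$period_start + 0:(span - 1L)

  ## stage 1: telemetry -----------------------------------------------------
  set.seed(config$rng_seed)
  dog_ids <- sprintf("dog%05d", seq_len(n))
  sdl <- config$between_dog_sdlog
  mu_s <- rlnorm(n, log(config$baseline_scratch_mean) - sdl^2 / 2, sdl)
  mu_l <- rlnorm(n, log(config$baseline_lick_mean) - sdl^2 / 2, sdl)

  N <- n * span
  behavior <- data.table(
    dog_id = rep(dog_ids, each = span),
    day = rep(seq_len(span), times = n),
    date = rep(dates, times = n)
  )
  full <- runif(N) < config$wear_prob
  pr <- config$partial_wear_fraction_range
  partial <- runif(N, pr[1], pr[2])
  behavior[, wear_fraction := fifelse(full, 1, partial)]

  # flares cluster within a dog-period around a dog-specific "itchy season"
  n_dp <- n * config$n_periods
  centre <- sample.int(config$period_length_days, n_dp, replace = TRUE) +
    rep((seq_len(config$n_periods) - 1L) * config$period_length_days, each = n)
  n_flares <- rpois(n_dp, config$flare_rate)
  flare_dp <- rep(seq_len(n_dp), n_flares)
  flare_dog <- (flare_dp - 1L) %% n + 1L
  flare_start <- as.integer(pmin(pmax(round(
    centre[flare_dp] + rnorm(length(flare_dp), 0, config$flare_cluster_sd)), 1L), span))
  behavior[, mult := 1]
  if (length(flare_dog)) {
    fl <- data.table(
      dog_id = rep(dog_ids[flare_dog], each = config$flare_duration_days),
      day = as.vector(vapply(flare_start,
                             function(s) s + seq_len(config$flare_duration_days) - 1L,
                             integer(config$flare_duration_days)))
    )
    fl <- unique(fl[day <= span])
    behavior[fl, mult := config$flare_magnitude, on = .(dog_id, day)]
  }
  k <- fifelse(behavior$mult > 1, config$flare_noise_shape, config$noise_shape)
  mu_s_row <- rep(mu_s, each = span)
  mu_l_row <- rep(mu_l, each = span)
  behavior[, scratch_seconds := rgamma(N, shape = k, rate = k / (mu_s_row * mult))]
  behavior[, lick_minutes    := rgamma(N, shape = k, rate = k / (mu_l_row * mult))]
  behavior[wear_fraction == 0, `:=`(scratch_seconds = 0, lick_minutes = 0)]
  behavior[, mult := NULL]

  ## internal alert pass (drives the owner response) ------------------------
  timeline <- build_timeline(behavior[, .(dog_id, date, scratch_seconds,
                                          lick_minutes, wear_fraction)],
                             thresholds = thresholds)
  alerts <- generate_alerts(timeline, period_start = config$period_start,
                            period_length_days = config$period_length_days)

  ## stage 2: background visits ---------------------------------------------
  set.seed(config$rng_seed + 1L)
  n_visits <- rpois(n, config$baseline_visit_rate * config$n_periods)
  vis_dog <- rep(dog_ids, n_visits)
  base_visits <- data.table(
    dog_id = vis_dog,
    day = if (length(vis_dog)) sample.int(span, length(vis_dog), replace = TRUE) else integer(0)
  )
  base_visits[, derm := runif(.N) < config$baseline_dermatitis_prob]

  ## stage 3: owner-response visits ------------------------------------------
  set.seed(config$rng_seed + 2L)
  nA <- nrow(alerts)
  if (nA) {
    u <- runif(nA)
    lag_p <- 1 / (1 + config$response_lag_mean)
    lag <- sample(0:28, nA, replace = TRUE,
                  prob = (1 - lag_p)^(0:28) * lag_p)
    derm_u <- runif(nA)
    r <- fifelse(alerts$period == 1L, config$response_prob_pre,
                 config$response_prob_post)
    take <- u < r
    induced <- data.table(
      dog_id = alerts$dog_id[take],
      day = as.integer(alerts$date[take] - config$period_start) + 1L + lag[take],
      derm = derm_u[take] < config$dermatitis_outcome_prob
    )[day <= span]
  } else {
    induced <- data.table(dog_id = character(0), day = integer(0), derm = logical(0))
  }
  visits <- rbind(base_visits, induced)
  visits <- visits[, .(dermatitis_outcome = any(derm)), by = .(dog_id, day)]
  setorder(visits, dog_id, day)
  visits[, visit_id := sprintf("v%07d", seq_len(.N))]
  visits[, date := config$period_start + day - 1L]
  visits <- visits[, .(visit_id, dog_id, date, dermatitis_outcome)]

  ## stage 4: prescriptions ---------------------------------------------------
  set.seed(config$rng_seed + 3L)
  lambda <- fifelse(visits$dermatitis_outcome, config$rx_rate_dermatitis,
                    config$rx_rate_other)
  n_rx <- rpois(nrow(visits), lambda)
  all_drugs <- unique(unlist(drug_catalogue(), use.names = FALSE))
  n_rx <- pmin(n_rx, length(all_drugs))
  rx_rows <- which(n_rx > 0)
  if (length(rx_rows)) {
    drugs <- lapply(rx_rows, function(i) sample(all_drugs, n_rx[i]))
    prescriptions <- data.table(
      visit_id = rep(visits$visit_id[rx_rows], n_rx[rx_rows]),
      drug_name = unlist(drugs)
    )
  } else {
    prescriptions <- data.table(visit_id = character(0), drug_name = character(0))
  }
  prescriptions[, prescription_id := sprintf("rx%07d", seq_len(.N))]
  prescriptions[, category := classify_drug(drug_name)]
  setcolorder(prescriptions, c("prescription_id", "visit_id", "drug_name", "category"))

  structure(list(behavior = behavior[, .(dog_id, date, scratch_seconds,
                                         lick_minutes, wear_fraction)],
                 visits = visits,
                 prescriptions = prescriptions,
                 config = config),
            class = "cohort_sim")
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf("Simulated cohort: %d dogs, %d dog-days, %d visits, %d prescriptions\n",
              x$config$n_dogs, nrow(x$behavior), nrow(x$visits),
              nrow(x$prescriptions)))
  invisible(x)
}

#' Write the three cohort tables as CSV
#'
#' Writes `behavior.csv`, `visits.csv` and `prescriptions.csv` (ISO-8601
#' dates, header row) into `dir`.
#'
#' @param sim A `cohort_sim` from [simulate_cohort()].
#' @param dir Output directory, created if needed.
#' @return Named character vector of the file paths, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(behavior = file.path(dir, "behavior.csv"),
             visits = file.path(dir, "visits.csv"),
             prescriptions = file.path(dir, "prescriptions.csv"))
  fwrite(sim$behavior, paths["behavior"])
  fwrite(sim$visits, paths["visits"])
  fwrite(sim$prescriptions, paths["prescriptions"])
  invisible(paths)
}

#' Read cohort tables written by [write_cohort()]
#'
#' @param dir Directory holding `behavior.csv`, `visits.csv`,
#'   `prescriptions.csv`.
#' @return A list with `behavior`, `visits`, `prescriptions` data.tables.
#' @export
read_cohort <- function(dir) {
  paths <- file.path(dir, c("behavior.csv", "visits.csv", "prescriptions.csv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "), call. = FALSE)
  behavior <- fread(paths[1])
  visits <- fread(paths[2])
  prescriptions <- fread(paths[3])
  behavior[, date := as.Date(date)]
  visits[, date := as.Date(date)]
  list(behavior = behavior, visits = visits, prescriptions = prescriptions)
}
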