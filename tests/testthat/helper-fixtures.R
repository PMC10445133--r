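# Small hand-built cohort pieces used across tests.

make_behavior <- function(dog_id, scratch, lick = rep(1, length(scratch)),
                          wear = rep(1, length(scratch)),
                          start = as.Date("2019-01-02")) {
  data.frame(dog_id = dog_id,
             date = start + seq_along(scratch) - 1L,
             scratch_seconds = scratch,
             lick_minutes = lick,
             wear_fraction = wear)
}

make_visits <- function(dog_id, days, derm = rep(FALSE, length(days)),
                        start = as.Date("2019-01-02")) {
  data.frame(visit_id = sprintf("v%03d", seq_along(days)),
             dog_id = dog_id,
             date = start + days - 1L,
             dermatitis_outcome = derm)
}

make_alerts <- function(dog_id, days, start = as.Date("2019-01-02")) {
  data.frame(alert_id = sprintf("a%03d", seq_along(days)),
             dog_id = dog_id,
             date = start + days - 1L)
}

small_config <- function(rng_seed = 404, ...) {
  cohort_config(n_dogs = 30, period_length_days = 60, rng_seed = rng_seed, ...)
}
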