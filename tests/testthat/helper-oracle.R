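# Independent brute-force re-implementations used as oracles. These are
# deliberately plain day-by-day loops with no shared code with the package.

oracle_levels <- function(x, bounds) {
  if (is.na(x)) return(NA_integer_)
  lev <- 0L
  for (b in bounds) if (x >= b) lev <- lev + 1L
  lev
}

# Brute-force alert recomputation for one cohort's behavior table.
# Trailing 7-day window including today; rolling mean over worn days only;
# sufficiency = wear-fraction sum >= 3.5 over a complete 7-day window;
# comparison day = latest prior day with a level, at most 7 days back;
# alerts only from usage day 9 (counted from first worn day).
oracle_alerts <- function(behavior, scratch_bounds = c(53, 120, 300),
                          lick_bounds = c(7, 19, 43)) {
  behavior <- as.data.frame(behavior)
  behavior <- behavior[order(behavior$dog_id, behavior$date), ]
  out <- list()
  for (dog in unique(behavior$dog_id)) {
    db <- behavior[behavior$dog_id == dog, ]
    T_ <- nrow(db)
    s_lev <- rep(NA_integer_, T_); l_lev <- rep(NA_integer_, T_)
    worn_any <- which(db$wear_fraction > 0)
    first_wear <- if (length(worn_any)) worn_any[1] else NA_integer_
    for (t in seq_len(T_)) {
      if (t < 7) next
      idx <- (t - 6):t
      if (sum(db$wear_fraction[idx]) < 3.5) next
      w <- idx[db$wear_fraction[idx] > 0]
      if (!length(w)) next
      s_lev[t] <- oracle_levels(mean(db$scratch_seconds[w]), scratch_bounds)
      l_lev[t] <- oracle_levels(mean(db$lick_minutes[w]), lick_bounds)
    }
    for (t in seq_len(T_)) {
      if (is.na(s_lev[t])) next
      if (is.na(first_wear) || (t - first_wear + 1L) < 9L) next
      prev <- NA_integer_
      for (back in 1:7) {
        if (t - back < 1) break
        if (!is.na(s_lev[t - back])) { prev <- t - back; break }
      }
      if (is.na(prev)) next
      s_up <- s_lev[t] > s_lev[prev]
      l_up <- l_lev[t] > l_lev[prev]
      if (!s_up && !l_up) next
      out[[length(out) + 1L]] <- data.frame(
        dog_id = dog, date = db$date[t],
        trigger = if (s_up && l_up) "both" else if (s_up) "scratch" else "lick",
        scratch_level_at_alert = s_lev[t], lick_level_at_alert = l_lev[t],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(dog_id = character(0), date = as.Date(character(0)),
                      trigger = character(0), scratch_level_at_alert = integer(0),
                      lick_level_at_alert = integer(0)))
  do.call(rbind, out)
}

# Quadratic-time greedy matcher: each alert, in date order, takes the
# earliest unconsumed visit with 0 <= lag <= window.
oracle_match <- function(alerts, visits, window = 28) {
  alerts <- as.data.frame(alerts)[order(as.data.frame(alerts)$dog_id,
                                        as.data.frame(alerts)$date), ]
  visits <- as.data.frame(visits)
  used <- rep(FALSE, nrow(visits))
  res <- list()
  for (i in seq_len(nrow(alerts))) {
    cand <- which(!used & visits$dog_id == alerts$dog_id[i] &
                    as.numeric(visits$date) >= as.numeric(alerts$date[i]) &
                    as.numeric(visits$date) <= as.numeric(alerts$date[i]) + window)
    if (!length(cand)) next
    j <- cand[which.min(as.numeric(visits$date[cand]))]
    used[j] <- TRUE
    res[[length(res) + 1L]] <- data.frame(
      alert_id = alerts$alert_id[i], visit_id = visits$visit_id[j],
      lag_days = as.integer(as.numeric(visits$date[j]) - as.numeric(alerts$date[i])))
  }
  if (!length(res))
    return(data.frame(alert_id = character(0), visit_id = character(0),
                      lag_days = integer(0)))
  do.call(rbind, res)
}
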