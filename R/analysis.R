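#' Run the full alert-visit analysis on cohort tables
#'
#' End-to-end analysis of a (simulated or imported) cohort: builds level
#' timelines, generates alerts, restricts each period to its eligible dogs
#' (at least one alert and one visit dated in the period), matches alerts to
#' first qualifying visits within the attribution window separately per
#' period, assigns dermatitis subgroups from first-period visit histories,
#' tabulates matches by week of lag and subgroup, builds the 2x2 odds-ratio
#' tables (combined and stratified by level at alert), and flags
#' prescriptions dispensed within the window after an alert.
#'
#' @param behavior,visits Cohort tables (see [simulate_cohort()] for the
#'   schemas).
#' @param prescriptions Optional prescription table; when given, per-period
#'   medication attribution fractions are computed.
#' @param period_start First study day.
#' @param period_length_days,n_periods Study layout (analysis expects two
#'   periods: 1 = control, 2 = exposure).
#' @param thresholds [level_thresholds()] for the level assignment.
#' @param window_days Attribution window (days).
#' @return A list of class `cohort_analysis`; see Details. Key elements:
#'   `alerts`, `eligible` (per-period dog ids), `matches` (with `period`),
#'   `alert_summaries`, `tables` (named list `combined`/`scratch`/`lick` of
#'   2x2 tables with odds-ratio columns), `week_bins` (per period and
#'   dermatitis subgroup), `subgroups`, `visit_counts`, `medications`.
#' @export
analyze_cohort <- function(behavior, visits, prescriptions = NULL,
                           period_start = min(as.Date(behavior$date)),
                           period_length_days = 292L, n_periods = 2L,
                           thresholds = level_thresholds(),
                           window_days = 28L) {
  if (n_periods != 2L)
    stop("the pre/post comparison needs exactly two periods", call. = FALSE)
  period_start <- as.Date(period_start)
  visits <- as.data.table(visits)
  visits[, date := as.Date(date)]

  timeline <- build_timeline(behavior, thresholds = thresholds)
  alerts <- generate_alerts(timeline, period_start = period_start,
                            period_length_days = period_length_days)

  p_bounds <- lapply(1:2, function(p) {
    s <- period_start + (p - 1L) * period_length_days
    c(s, s + period_length_days - 1L)
  })
  eligible <- lapply(1:2, function(p)
    eligible_dogs(alerts, visits, p, period_start, period_length_days))

  per_period <- lapply(1:2, function(p) {
    al <- alerts[period == p & dog_id %in% eligible[[p]]]
    vi <- visits[dog_id %in% eligible[[p]] &
                   date >= p_bounds[[p]][1] & date <= p_bounds[[p]][2]]
    m <- match_alert_visits(al, vi, window_days = window_days)
    list(alerts = al, visits = vi, matches = m)
  })
  matches <- rbindlist(lapply(1:2, function(p)
    cbind(per_period[[p]]$matches, period = p)))

  alert_summaries <- lapply(1:2, function(p)
    summarize_alerts(per_period[[p]]$alerts, eligible[[p]]))

  analysis_alerts <- rbindlist(lapply(per_period, `[[`, "alerts"))
  tables <- list(
    combined = add_odds_ratios(build_two_by_two(analysis_alerts, matches, "none")),
    scratch = add_odds_ratios(build_two_by_two(analysis_alerts, matches, "scratch_level")),
    lick = add_odds_ratios(build_two_by_two(analysis_alerts, matches, "lick_level"))
  )

  subgroups <- assign_subgroups(visits, p_bounds[[1]][1], p_bounds[[1]][2],
                                dogs = unique(c(eligible[[1]], eligible[[2]])))

  week_bins <- rbindlist(lapply(1:2, function(p) {
    vi <- merge(per_period[[p]]$visits, subgroups, by = "dog_id", all.x = TRUE)
    mm <- merge(per_period[[p]]$matches, subgroups, by = "dog_id", all.x = TRUE)
    rows <- lapply(0:3, function(g) {
      cbind(data.table(period = p, group = g),
            bin_matches_by_week(mm[group == g], total_visits = vi[group == g, .N]))
    })
    total <- cbind(data.table(period = p, group = NA_integer_),
                   bin_matches_by_week(mm, total_visits = nrow(vi)))
    rbindlist(c(rows, list(total)))
  }))

  visit_counts <- vapply(per_period, function(x) nrow(x$visits), integer(1))

  medications <- NULL
  if (!is.null(prescriptions) && nrow(prescriptions)) {
    rx <- attribute_prescriptions(prescriptions, visits, alerts,
                                  window_days = window_days)
    rx <- merge(rx, visits[, .(visit_id, dog_id, date)], by = "visit_id")
    medications <- rbindlist(lapply(1:2, function(p) {
      in_p <- rx[dog_id %in% eligible[[p]] &
                   date >= p_bounds[[p]][1] & date <= p_bounds[[p]][2]]
      data.table(period = p, n_medications = nrow(in_p),
                 n_within_window = in_p[within_4wk_of_alert == TRUE, .N],
                 pct_within_window = if (nrow(in_p)) pct(in_p[within_4wk_of_alert == TRUE, .N], nrow(in_p)) else NA_real_)
    }))
  }

  structure(list(
    alerts = alerts, eligible = eligible, matches = matches,
    alert_summaries = alert_summaries, tables = tables,
    week_bins = week_bins, subgroups = subgroups,
    visit_counts = visit_counts, medications = medications,
    window_days = window_days, period_start = period_start,
    period_length_days = period_length_days
  ), class = "cohort_analysis")
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat("Alert-visit analysis, two", x$period_length_days, "day periods\n")
  for (p in 1:2) {
    s <- x$alert_summaries[[p]]
    frac <- pct(x$matches[period == p, .N], max(s$total_alerts, 1))
    cat(sprintf("  period %d: %d dogs, %d alerts (mean %.1f/dog), %d alert visits (%.2f%% of alerts)\n",
                p, s$n_dogs, s$total_alerts, s$mean_per_dog,
                x$matches[period == p, .N], frac))
  }
  comb <- x$tables$combined
  cat(sprintf("  combined OR %.4f (95%% CI %.2f-%.2f)\n",
              comb$odds_ratio, comb$ci_low, comb$ci_high))
  invisible(x)
}
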