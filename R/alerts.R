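#' Generate pruritus alerts from a level timeline
#'
#' An alert is emitted for a dog-day when the scratch and/or lick severity
#' level has risen by one or more levels relative to the comparison day, the
#' day and the comparison day both satisfy the data-sufficiency rule, and the
#' day is at least day 9 of consecutive collar usage (the first 7 usage days
#' form the baseline period; the earliest possible alert falls on day 9).
#' The comparison day is the most recent prior day with a defined level,
#' looked back at most `max_lookback_days`; with no such day, no alert is
#' emitted. A simultaneous rise in both metrics yields a single alert with
#' trigger `"both"`, so there is at most one alert per dog-day.
#'
#' @param timeline A timeline from [build_timeline()].
#' @param period_start First study day, used to tag alerts with their period.
#' @param period_length_days Days per study period.
#' @param min_usage_day Earliest eligible day of consecutive usage.
#' @param max_lookback_days Maximum age, in days, of the comparison day.
#' @return A `data.table` with columns `alert_id`, `dog_id`, `date`,
#'   `trigger` (`"scratch"`, `"lick"` or `"both"`), `scratch_level_at_alert`,
#'   `lick_level_at_alert`, `period`, ordered by dog and date.
#' @export
generate_alerts <- function(timeline,
                            period_start = min(timeline$date),
                            period_length_days = 292L,
                            min_usage_day = 9L,
                            max_lookback_days = 7L) {
  need <- c("dog_id", "date", "scratch_level", "lick_level", "sufficient",
            "has_level", "usage_day")
  miss <- setdiff(need, names(timeline))
  if (length(miss))
    stop("timeline lacks column(s): ", paste(miss, collapse = ", "),
         " (compute it with build_timeline())", call. = FALSE)
  dt <- as.data.table(timeline)[has_level == TRUE,
                                .(dog_id, date, scratch_level, lick_level, usage_day)]
  setkey(dt, dog_id, date)
  dt[, `:=`(
    prev_day     = shift(as.integer(date)),
    prev_scratch = shift(scratch_level),
    prev_lick    = shift(lick_level)
  ), by = dog_id]
  dt[, gap := as.integer(date) - prev_day]
  alerts <- dt[!is.na(prev_day) & gap <= max_lookback_days &
                 usage_day >= min_usage_day &
                 (scratch_level > prev_scratch | lick_level > prev_lick)]
  alerts[, trigger := fifelse(scratch_level > prev_scratch & lick_level > prev_lick, "both",
                       fifelse(scratch_level > prev_scratch, "scratch", "lick"))]
  alerts[, period := period_of_day(as.integer(date - as.Date(period_start)) + 1L,
                                   period_length_days)]
  out <- alerts[, .(dog_id, date,
                    trigger,
                    scratch_level_at_alert = scratch_level,
                    lick_level_at_alert = lick_level,
                    period)]
  setorder(out, dog_id, date)
  out[, alert_id := sprintf("a%07d", seq_len(.N))]
  setcolorder(out, c("alert_id", "dog_id", "date", "trigger",
                     "scratch_level_at_alert", "lick_level_at_alert", "period"))
  out[]
}

#' Summarize alert burden for one study period
#'
#' Totals and the per-dog distribution of alerts over a stated set of
#' eligible dogs; dogs in the set with zero alerts count in the denominator.
#'
#' @param alerts Alert table (as from [generate_alerts()]), already filtered
#'   to the period of interest.
#' @param dogs Character vector of eligible dog ids for the period.
#' @return A list of class `alert_summary`: `total_alerts`, `n_dogs`,
#'   `mean_per_dog`, `median_per_dog`, `max_per_dog`, `min_per_dog`, `range`
#'   (max minus min).
#' @export
summarize_alerts <- function(alerts, dogs) {
  if (length(dogs) == 0L) stop("empty eligible dog set", call. = FALSE)
  counts <- as.data.table(alerts)[dog_id %in% dogs, .N, by = dog_id]
  per_dog <- setNames(rep(0L, length(dogs)), dogs)
  per_dog[counts$dog_id] <- counts$N
  structure(list(
    total_alerts = sum(per_dog),
    n_dogs = length(dogs),
    mean_per_dog = sum(per_dog) / length(dogs),
    median_per_dog = median(per_dog),
    max_per_dog = max(per_dog),
    min_per_dog = min(per_dog),
    range = max(per_dog) - min(per_dog)
  ), class = "alert_summary")
}

#' @export
print.alert_summary <- function(x, ...) {
  cat(sprintf("%d alerts over %d dogs: mean %.1f, median %.1f, max %d, range %d\n",
              x$total_alerts, x$n_dogs, x$mean_per_dog, x$median_per_dog,
              x$max_per_dog, x$range))
  invisible(x)
}

#' Dogs eligible for a period's analysis
#'
#' A dog enters a period's dataset when it has at least one alert and at
#' least one clinic visit dated within that period.
#'
#' @param alerts Alert table with `period` column.
#' @param visits Visit table with `dog_id`, `date`.
#' @param period Period number.
#' @param period_start,period_length_days Study layout used to date-bound the
#'   period.
#' @return Character vector of dog ids.
#' @export
eligible_dogs <- function(alerts, visits, period, period_start,
                          period_length_days = 292L) {
  want_period <- period
  p0 <- as.Date(period_start) + (want_period - 1L) * period_length_days
  p1 <- p0 + period_length_days - 1L
  a <- unique(as.data.table(alerts)[period == want_period, dog_id])
  v <- unique(as.data.table(visits)[date >= p0 & date <= p1, dog_id])
  sort(intersect(a, v))
}
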