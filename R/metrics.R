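#' Severity-level thresholds for rolling scratch and lick averages
#'
#' The four ordered severity bands used by the alerting system are
#' infrequent (0), occasional (1), elevated (2) and severe (3). Bands are
#' half-open and lower-inclusive: level 0 on `[0, c1)`, 1 on `[c1, c2)`,
#' 2 on `[c2, c3)` and 3 on `[c3, Inf)`. The default cut points are
#' 53/120/300 s/day for scratching and 7/19/43 min/day for licking, so a
#' rolling scratch average of 52 is infrequent and 53 is occasional.
#'
#' @param scratch_bounds Three strictly ascending positive cut points, s/day.
#' @param lick_bounds Three strictly ascending positive cut points, min/day.
#' @return A list of class `level_thresholds`.
#' @examples
#' th <- level_thresholds()
#' categorize_level(c(0, 52, 53, 299, 300), "scratch", th)
#' @export
level_thresholds <- function(scratch_bounds = c(53, 120, 300),
                             lick_bounds = c(7, 19, 43)) {
  for (nm in c("scratch_bounds", "lick_bounds")) {
    b <- get(nm)
    if (length(b) != 3L || any(is.na(b)) || any(b <= 0) || any(diff(b) <= 0))
      stop("'", nm, "' must be three strictly ascending positive cut points",
           call. = FALSE)
  }
  structure(list(scratch_bounds = as.numeric(scratch_bounds),
                 lick_bounds = as.numeric(lick_bounds)),
            class = "level_thresholds")
}

#' Ordered severity level labels
#'
#' @return Character vector of the four labels, in ascending severity, named
#'   by their integer codes 0-3.
#' @export
level_labels <- function() {
  c(`0` = "infrequent", `1` = "occasional", `2` = "elevated", `3` = "severe")
}

#' Assign severity levels to rolling behaviour averages
#'
#' @param value Numeric vector of nonnegative rolling averages (s/day for
#'   scratch, min/day for lick). `NA` values yield `NA` levels.
#' @param metric `"scratch"` or `"lick"`.
#' @param thresholds A [level_thresholds()] object.
#' @return Integer vector of levels 0-3 (see [level_labels()]).
#' @export
categorize_level <- function(value, metric = c("scratch", "lick"),
                             thresholds = level_thresholds()) {
  metric <- match.arg(metric)
  if (any(value < 0, na.rm = TRUE))
    stop("behaviour values must be nonnegative", call. = FALSE)
  bounds <- if (metric == "scratch") thresholds$scratch_bounds else thresholds$lick_bounds
  # findInterval with left-closed bins: value == cut point goes up a level
  lev <- findInterval(value, bounds, left.open = FALSE)
  as.integer(lev)
}

#' Trailing 7-day rolling mean over worn days
#'
#' Each day's value is the mean of that day's and the preceding six days'
#' behaviour values, taken over days with any collar wear
#' (`wear_fraction > 0`). No-wear days are excluded from the mean; a window
#' with zero worn days, or fewer than seven days of history, yields `NA`.
#'
#' @param values Numeric vector of daily behaviour values, one per calendar
#'   day, date-contiguous.
#' @param wear_fraction Numeric vector in \[0, 1\], same length as `values`.
#' @param dates Optional `Date` vector used to verify contiguity.
#' @return Numeric vector of rolling means (`NA` where undefined).
#' @examples
#' rolling_mean_7(c(0, 0, 0, 0, 0, 0, 70), rep(1, 7))  # day 7: 10
#' @export
rolling_mean_7 <- function(values, wear_fraction, dates = NULL) {
  if (length(values) != length(wear_fraction))
    stop("'values' and 'wear_fraction' must have the same length", call. = FALSE)
  if (!is.null(dates)) {
    if (length(dates) != length(values) ||
        (length(dates) > 1L && any(diff(as.integer(as.Date(dates))) != 1L)))
      stop("dates must be contiguous calendar days", call. = FALSE)
  }
  worn <- wear_fraction > 0
  s <- data.table::frollsum(ifelse(worn, values, 0), 7)
  n <- data.table::frollsum(as.numeric(worn), 7)
  out <- s / n
  out[!is.na(n) & n == 0] <- NA_real_
  out
}

#' Data-sufficiency rule for a 7-day window
#'
#' A day has sufficient data when the wear fractions of its trailing 7-day
#' window sum to at least `minimum` days (default 3.5). The sum counts
#' fractional wear, so e.g. fractions `c(1, 1, 1, 0.5, 0, 0, 0)` qualify.
#'
#' @param window Numeric vector of exactly 7 wear fractions in \[0, 1\].
#' @param minimum Minimum wear-day total.
#' @return Logical scalar.
#' @export
wear_sufficient <- function(window, minimum = 3.5) {
  if (length(window) != 7L)
    stop("'window' must contain exactly 7 wear fractions", call. = FALSE)
  if (any(is.na(window)) || any(window < 0) || any(window > 1))
    stop("wear fractions must lie in [0, 1]", call. = FALSE)
  sum(window) >= minimum
}

#' Build per-dog level timelines from daily behaviour records
#'
#' Computes, for every dog-day: the trailing 7-day rolling scratch and lick
#' means over worn days, the data-sufficiency flag (wear-fraction sum over
#' the trailing 7 days at least `min_wear_days`), severity levels where both
#' the sufficiency rule holds and a rolling value exists, and the day of
#' consecutive usage counted from the dog's first worn day.
#'
#' @param behavior A data.frame/data.table with columns `dog_id`, `date`
#'   (contiguous per dog), `scratch_seconds`, `lick_minutes`, `wear_fraction`.
#' @param thresholds A [level_thresholds()] object.
#' @param min_wear_days Sufficiency minimum, in (fractional) wear days.
#' @return A `data.table` keyed by (`dog_id`, `date`) with columns
#'   `rolling_scratch`, `rolling_lick`, `scratch_level`, `lick_level`,
#'   `sufficient`, `has_level`, `usage_day`.
#' @export
build_timeline <- function(behavior, thresholds = level_thresholds(),
                           min_wear_days = 3.5) {
  need <- c("dog_id", "date", "scratch_seconds", "lick_minutes", "wear_fraction")
  miss <- setdiff(need, names(behavior))
  if (length(miss))
    stop("behaviour table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  dt <- as.data.table(behavior)[, ..need]
  dt[, date := as.Date(date)]
  setkey(dt, dog_id, date)
  if (anyDuplicated(dt, by = c("dog_id", "date")))
    stop("behaviour table has duplicate dog-day records", call. = FALSE)
  bad <- dt[, any(diff(as.integer(date)) != 1L), by = dog_id][V1 == TRUE]
  if (nrow(bad))
    stop("behaviour dates are not contiguous for dog(s): ",
         paste(head(bad$dog_id, 3), collapse = ", "), call. = FALSE)

  dt[, worn := wear_fraction > 0]
  dt[, `:=`(
    wsum7  = data.table::frollsum(wear_fraction, 7),
    nworn7 = data.table::frollsum(as.numeric(worn), 7),
    ssum7  = data.table::frollsum(fifelse(worn, scratch_seconds, 0), 7),
    lsum7  = data.table::frollsum(fifelse(worn, lick_minutes, 0), 7)
  ), by = dog_id]
  dt[, rolling_scratch := fifelse(!is.na(nworn7) & nworn7 > 0, ssum7 / nworn7, NA_real_)]
  dt[, rolling_lick    := fifelse(!is.na(nworn7) & nworn7 > 0, lsum7 / nworn7, NA_real_)]
  dt[, sufficient := !is.na(wsum7) & wsum7 >= min_wear_days]
  dt[, has_level := sufficient & !is.na(rolling_scratch)]
  dt[, scratch_level := fifelse(has_level,
                                categorize_level(fifelse(has_level, rolling_scratch, 0),
                                                 "scratch", thresholds),
                                NA_integer_)]
  dt[, lick_level := fifelse(has_level,
                             categorize_level(fifelse(has_level, rolling_lick, 0),
                                              "lick", thresholds),
                             NA_integer_)]
  dt[, first_wear_day := {
    w <- which(worn)
    if (length(w)) as.integer(date[w[1]]) else NA_integer_
  }, by = dog_id]
  dt[, usage_day := as.integer(date) - first_wear_day + 1L]
  dt[, c("wsum7", "ssum7", "lsum7", "first_wear_day") := NULL]
  dt[]
}
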