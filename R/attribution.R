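#' Match alerts to the first qualifying clinic visit
#'
#' Implements the alert-visit rule: per dog, alerts are processed in
#' chronological order and each pairs with the earliest not-yet-matched visit
#' whose date lies 0 to `window_days` days after the alert. Matching is
#' strictly one-to-one — a visit, once consumed, is never an alert visit for
#' a later alert, and visits that precede every alert or fall outside every
#' window are never matched. A same-day visit (lag 0) is within the window
#' and falls in week bin 1.
#'
#' @param alerts Alert table with `alert_id`, `dog_id`, `date`.
#' @param visits Visit table with `visit_id`, `dog_id`, `date`.
#' @param window_days Attribution window in days (default 28 = 4 weeks).
#' @return A `data.table` with columns `alert_id`, `visit_id`, `dog_id`,
#'   `lag_days`, `week_bin` (1-4 for windows up to 28 days; lag 0 counts in
#'   bin 1).
#' @export
match_alert_visits <- function(alerts, visits, window_days = 28L) {
  if (length(window_days) != 1L || is.na(window_days) || window_days < 0)
    stop("invalid configuration: 'window_days' must be nonnegative", call. = FALSE)
  a <- as.data.table(alerts)[, .(alert_id, dog_id, day = as.integer(as.Date(date)))]
  v <- as.data.table(visits)[, .(visit_id, dog_id, day = as.integer(as.Date(date)))]
  setorder(a, dog_id, day)
  setorder(v, dog_id, day)
  common <- intersect(unique(a$dog_id), unique(v$dog_id))
  res <- vector("list", length(common))
  vi <- split(seq_len(nrow(v)), v$dog_id)
  ai <- split(seq_len(nrow(a)), a$dog_id)
  for (k in seq_along(common)) {
    dog <- common[k]
    arow <- ai[[dog]]
    vday <- v$day[vi[[dog]]]
    vid <- v$visit_id[vi[[dog]]]
    nv <- length(vday)
    j <- 1L
    m_alert <- character(0); m_visit <- character(0); m_lag <- integer(0)
    for (i in arow) {
      ad <- a$day[i]
      while (j <= nv && vday[j] < ad) j <- j + 1L
      if (j > nv) break
      if (vday[j] <= ad + window_days) {
        m_alert <- c(m_alert, a$alert_id[i])
        m_visit <- c(m_visit, vid[j])
        m_lag <- c(m_lag, vday[j] - ad)
        j <- j + 1L
      }
    }
    if (length(m_alert))
      res[[k]] <- data.table(alert_id = m_alert, visit_id = m_visit,
                             dog_id = dog, lag_days = m_lag)
  }
  out <- rbindlist(res)
  if (!nrow(out))
    return(data.table(alert_id = character(0), visit_id = character(0),
                      dog_id = character(0), lag_days = integer(0),
                      week_bin = integer(0)))
  out[, week_bin := as.integer(ceiling(pmax(lag_days, 1L) / 7))]
  out[]
}

#' Assign dermatitis subgroups from first-period visit histories
#'
#' Dogs are stratified by their count of first-period clinic visits carrying
#' a dermatitis outcome: 0 visits gives Group 0, 1 visit Group 1, 2-5 visits
#' Group 2 and 6 or more Group 3. Dogs with no first-period visits at all
#' are Group 0.
#'
#' @param visits Visit table with `dog_id`, `date`, `dermatitis_outcome`.
#' @param period1_start,period1_end Date bounds (inclusive) of the first
#'   period.
#' @param dogs Dog ids to assign; defaults to the dogs present in `visits`.
#' @return A `data.table` with columns `dog_id`, `group` (integer 0-3).
#' @export
assign_subgroups <- function(visits, period1_start, period1_end,
                             dogs = unique(visits$dog_id)) {
  v <- as.data.table(visits)
  counts <- v[date >= as.Date(period1_start) & date <= as.Date(period1_end) &
                dermatitis_outcome == TRUE, .N, by = dog_id]
  out <- data.table(dog_id = sort(unique(as.character(dogs))))
  out <- merge(out, counts, by = "dog_id", all.x = TRUE)
  out[is.na(N), N := 0L]
  out[, group := fifelse(N == 0L, 0L,
                  fifelse(N == 1L, 1L,
                   fifelse(N <= 5L, 2L, 3L)))]
  out[, N := NULL]
  out[]
}

#' Flag prescriptions dispensed within the post-alert window
#'
#' A prescription is flagged when the date of its visit lies 0 to
#' `window_days` days after any alert of the same dog; the flag is a function
#' of the visit date only, so all prescriptions of a qualifying visit are
#' flagged.
#'
#' @param prescriptions Prescription table with `prescription_id`, `visit_id`.
#' @param visits Visit table with `visit_id`, `dog_id`, `date`.
#' @param alerts Alert table with `dog_id`, `date`.
#' @param window_days Attribution window in days.
#' @return `prescriptions` as a `data.table` with an added logical column
#'   `within_4wk_of_alert`.
#' @export
attribute_prescriptions <- function(prescriptions, visits, alerts,
                                    window_days = 28L) {
  rx <- as.data.table(prescriptions)
  v <- as.data.table(visits)[, .(visit_id, dog_id, day = as.integer(as.Date(date)))]
  orphan <- setdiff(rx$visit_id, v$visit_id)
  if (length(orphan))
    stop("prescription(s) reference unknown visit(s): ",
         paste(head(orphan, 3), collapse = ", "), call. = FALSE)
  a <- as.data.table(alerts)[, .(dog_id, start_day = as.integer(as.Date(date)))]
  a[, end_day := start_day + as.integer(window_days)]
  hit <- a[v, on = .(dog_id, start_day <= day, end_day >= day),
           nomatch = NULL][, unique(visit_id)]
  rx <- copy(rx)
  rx[, within_4wk_of_alert := visit_id %in% hit]
  rx[]
}

#' Tabulate alert-visit matches by week of lag
#'
#' @param matches Match table from [match_alert_visits()].
#' @param total_visits Optional total visit count used to report the number
#'   of visits falling outside every 4-week window.
#' @return A one-row `data.table` with counts `week1`-`week4`, `matched`
#'   (their sum) and, when `total_visits` is given, `outside_window`.
#' @export
bin_matches_by_week <- function(matches, total_visits = NULL) {
  m <- as.data.table(matches)
  counts <- vapply(1:4, function(w) sum(m$week_bin == w), integer(1))
  out <- data.table(week1 = counts[1], week2 = counts[2],
                    week3 = counts[3], week4 = counts[4],
                    matched = sum(counts))
  if (!is.null(total_visits)) out[, outside_window := as.integer(total_visits) - matched]
  out[]
}
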