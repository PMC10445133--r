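#' Odds ratio from a 2x2 table, log-method confidence interval
#'
#' For a table with `a` exposed events, `b` exposed non-events, `c` control
#' events and `d` control non-events, computes
#' \eqn{OR = (a/b) / (c/d)}, the standard error of the log odds ratio
#' \eqn{SE = \sqrt{1/a + 1/b + 1/c + 1/d}}, the 95% confidence interval
#' \eqn{\exp(\ln OR \pm 1.96\,SE)}, and the two-tailed normal p-value of
#' \eqn{z = \ln OR / SE}. If any single cell is zero, the Haldane-Anscombe
#' continuity correction adds 0.5 to all four cells; an entirely empty row
#' or column leaves the estimate undefined and is an error.
#'
#' @param a,b,c,d Nonnegative cell counts: events and non-events in the
#'   exposed (e.g. second-period) and control (first-period) groups.
#' @param conf_level Confidence level of the interval.
#' @return A list of class `odds_ratio_result`: `odds_ratio`, `log_se`,
#'   `ci_low`, `ci_high`, `z`, `p_two_tailed`, `corrected` (whether the 0.5
#'   correction was applied) and the (uncorrected) cell counts.
#' @examples
#' odds_ratio(6980, 86237, 5382, 108148)  # OR 1.6264, 95% CI 1.57-1.69
#' @export
odds_ratio <- function(a, b, c, d, conf_level = 0.95) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0))
    stop("cell counts must be nonnegative", call. = FALSE)
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0)
    stop("odds ratio undefined: a row or column of the 2x2 table is empty",
         call. = FALSE)
  corrected <- any(cells == 0)
  x <- if (corrected) cells + 0.5 else cells
  or <- (x["a"] / x["b"]) / (x["c"] / x["d"])
  se <- sqrt(sum(1 / x))
  zc <- qnorm(1 - (1 - conf_level) / 2)
  z <- log(or) / se
  structure(list(
    odds_ratio = unname(or),
    log_se = unname(se),
    ci_low = unname(exp(log(or) - zc * se)),
    ci_high = unname(exp(log(or) + zc * se)),
    z = unname(z),
    p_two_tailed = unname(2 * pnorm(-abs(z))),
    conf_level = conf_level,
    corrected = corrected,
    a = a, b = b, c = c, d = d
  ), class = "odds_ratio_result")
}

#' Format a p-value the way clinical reports print it
#'
#' @param p Numeric p-value(s).
#' @param floor Values below this print as `"<floor"`.
#' @return Character vector.
#' @export
format_p <- function(p, floor = 1e-4) {
  ifelse(p < floor, paste0("<", format(floor, scientific = FALSE)),
         formatC(p, digits = 4, format = "f"))
}

#' @export
print.odds_ratio_result <- function(x, ...) {
  cat(sprintf("OR %.4f (%.0f%% CI %.2f-%.2f), p %s%s\n",
              x$odds_ratio, 100 * x$conf_level, x$ci_low, x$ci_high,
              format_p(x$p_two_tailed),
              if (x$corrected) " [0.5 continuity correction]" else ""))
  invisible(x)
}

#' Build 2x2 tables of alert-visit association by period and stratum
#'
#' The event is "alert matched to a clinic visit within the attribution
#' window"; the second period (alerts visible to owners) is the exposure arm
#' and the first period the control arm. Optionally stratifies by the
#' scratch or lick severity level at the moment the alert was generated;
#' alerts triggered only by the other metric still carry a level for the
#' stratifying metric (often infrequent) and are counted in that stratum,
#' so each stratification partitions the same alert set and the combined
#' row totals agree across stratifications.
#'
#' @param alerts Alert table with `alert_id`, `period`,
#'   `scratch_level_at_alert`, `lick_level_at_alert`.
#' @param matches Match table from [match_alert_visits()] (or any table with
#'   an `alert_id` column listing the matched alerts).
#' @param stratify_by `"none"`, `"scratch_level"` or `"lick_level"`.
#' @return A `data.table` with one row per stratum plus a `"combined"` row:
#'   columns `stratum`, `a` (period-2 matched), `b` (period-2 unmatched),
#'   `c` (period-1 matched), `d` (period-1 unmatched).
#' @export
build_two_by_two <- function(alerts, matches,
                             stratify_by = c("none", "scratch_level", "lick_level")) {
  stratify_by <- match.arg(stratify_by)
  al <- as.data.table(alerts)
  al[, matched := alert_id %in% as.data.table(matches)$alert_id]
  if (!all(al$period %in% c(1L, 2L)))
    stop("2x2 construction needs exactly two periods (1 = control, 2 = exposure)",
         call. = FALSE)
  cell <- function(x) data.table(
    a = x[period == 2L & matched == TRUE, .N],
    b = x[period == 2L & matched == FALSE, .N],
    c = x[period == 1L & matched == TRUE, .N],
    d = x[period == 1L & matched == FALSE, .N])
  if (stratify_by == "none") {
    out <- cbind(data.table(stratum = "combined"), cell(al))
    return(out[])
  }
  col <- if (stratify_by == "scratch_level") "scratch_level_at_alert" else "lick_level_at_alert"
  labs <- level_labels()
  rows <- lapply(0:3, function(lv) {
    cbind(data.table(stratum = unname(labs[as.character(lv)])),
          cell(al[get(col) == lv]))
  })
  out <- rbindlist(c(rows, list(cbind(data.table(stratum = "combined"), cell(al)))))
  out[]
}

#' Add odds-ratio columns to a table of 2x2 counts
#'
#' @param tables A `data.table` with columns `a`, `b`, `c`, `d` (one 2x2
#'   table per row), as from [build_two_by_two()].
#' @return The table with appended columns `odds_ratio`, `ci_low`, `ci_high`,
#'   `z`, `p_two_tailed`.
#' @export
add_odds_ratios <- function(tables) {
  tb <- as.data.table(tables)
  res <- lapply(seq_len(nrow(tb)),
                function(i) odds_ratio(tb$a[i], tb$b[i], tb$c[i], tb$d[i]))
  tb[, `:=`(
    odds_ratio = vapply(res, `[[`, numeric(1), "odds_ratio"),
    ci_low = vapply(res, `[[`, numeric(1), "ci_low"),
    ci_high = vapply(res, `[[`, numeric(1), "ci_high"),
    z = vapply(res, `[[`, numeric(1), "z"),
    p_two_tailed = vapply(res, `[[`, numeric(1), "p_two_tailed")
  )]
  tb[]
}

#' Percentage of a count over a denominator
#'
#' @param numerator,denominator Counts; the denominator must be positive.
#' @return `100 * numerator / denominator`.
#' @examples
#' pct(5382, 113530)  # 4.74 (to 2 d.p.)
#' @export
pct <- function(numerator, denominator) {
  if (any(denominator <= 0)) stop("denominator must be positive", call. = FALSE)
  100 * numerator / denominator
}

#' Coverage of the log-method confidence interval by simulation
#'
#' Draws repeated 2x2 tables with binomial sampling at a fixed true odds
#' ratio and reports how often the 95% interval of [odds_ratio()] covers the
#' truth. Used to check the interval's calibration.
#'
#' @param true_or True odds ratio relating the exposed to the control event
#'   probability.
#' @param p_control Event probability in the control arm.
#' @param n_exposed,n_control Arm sizes per draw.
#' @param n_rep Number of simulated tables.
#' @param seed RNG seed.
#' @param conf_level Interval confidence level.
#' @return A list: `coverage` (proportion in \[0, 1\]), `n_rep`, `true_or`.
#' @export
ci_coverage_sim <- function(true_or, p_control, n_exposed, n_control,
                            n_rep = 500L, seed = 1L, conf_level = 0.95) {
  stopifnot(true_or > 0, p_control > 0, p_control < 1)
  odds_c <- p_control / (1 - p_control)
  p_exposed <- true_or * odds_c / (1 + true_or * odds_c)
  set.seed(seed)
  a <- rbinom(n_rep, n_exposed, p_exposed)
  c_ <- rbinom(n_rep, n_control, p_control)
  covered <- vapply(seq_len(n_rep), function(i) {
    res <- odds_ratio(a[i], n_exposed - a[i], c_[i], n_control - c_[i],
                      conf_level = conf_level)
    res$ci_low <= true_or && true_or <= res$ci_high
  }, logical(1))
  list(coverage = mean(covered), n_rep = n_rep, true_or = true_or)
}
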