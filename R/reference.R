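#' Published reference counts for the alert-visit comparison
#'
#' The package ships, as plain CSV fixtures, the 2x2 cell counts and summary
#' totals published for the large two-period retrospective activity-monitor
#' cohort that motivated this pipeline (7,191 / 6,684 dogs with 113,530 /
#' 93,217 alerts in the control and exposure periods). They allow the
#' statistics stage to be exercised and validated exactly, without
#' simulation.
#'
#' @return `reference_counts()`: a `data.table` with one 2x2 table per row
#'   (`stratification` in scratch/lick/combined, `stratum`, cells `a`, `b`,
#'   `c`, `d`, where `a`/`b` are exposure-period alerts with/without an
#'   associated 4-week visit and `c`/`d` the control-period equivalents).
#'   `reference_totals()`: a named numeric vector of cohort totals (alerts,
#'   visits, alert visits, medications and week-bin visit counts per period).
#' @export
reference_counts <- function() {
  path <- system.file("extdata", "reference_counts.csv", package = "itchalert",
                      mustWork = TRUE)
  fread(path)
}

#' @rdname reference_counts
#' @export
reference_totals <- function() {
  path <- system.file("extdata", "reference_totals.csv", package = "itchalert",
                      mustWork = TRUE)
  tot <- fread(path)
  setNames(tot$value, tot$key)
}

#' Odds ratios and descriptive fractions from the reference counts
#'
#' Recomputes, from the shipped reference counts alone, every statistic of
#' the published comparison: per-stratum and combined odds ratios with 95%
#' confidence intervals and p-values, the per-alert visit-association
#' fractions, the per-visit alert-visit fractions, the medication
#' attribution fractions and mean alerts per dog.
#'
#' @return A list: `odds_ratios` (a `data.table` of 2x2 rows with OR, CI and
#'   p columns) and `fractions` (named numeric vector, percentages except
#'   the means).
#' @examples
#' ref <- reference_statistics()
#' ref$odds_ratios[stratification == "combined"]
#' @export
reference_statistics <- function() {
  counts <- add_odds_ratios(reference_counts())
  tot <- reference_totals()
  fractions <- c(
    alert_fraction_pre_pct = pct(tot["alert_visits_pre"], tot["alerts_pre"]),
    alert_fraction_post_pct = pct(tot["alert_visits_post"], tot["alerts_post"]),
    visit_fraction_pre_pct = pct(tot["alert_visits_pre"], tot["visits_pre"]),
    visit_fraction_post_pct = pct(tot["alert_visits_post"], tot["visits_post"]),
    medication_fraction_pre_pct = pct(tot["medications_within_4wk_pre"], tot["medications_pre"]),
    medication_fraction_post_pct = pct(tot["medications_within_4wk_post"], tot["medications_post"]),
    mean_alerts_per_dog_pre = unname(tot["alerts_pre"] / tot["dogs_pre"]),
    mean_alerts_per_dog_post = unname(tot["alerts_post"] / tot["dogs_post"])
  )
  names(fractions) <- sub("\\..*$", "", names(fractions))
  list(odds_ratios = counts, fractions = fractions)
}
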