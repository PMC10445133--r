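# itchalert

Pruritus alert generation and clinic-visit attribution for canine
activity-monitor cohorts.

## What this is for

Collar-mounted accelerometers can report how long a dog scratches
(seconds/day) and licks itself (minutes/day), and can push a digital
*pruritus alert* to the owner when those behaviours rise. `itchalert`
implements the full analytical pipeline used to ask whether such alerts
change owner behaviour in a two-period retrospective design — two
consecutive 292-day intervals in which the alerting algorithm runs
identically, but alerts are visible to owners only in the second:

* **Alert engine** — trailing 7-day rolling averages over worn days;
  ordinal severity levels (infrequent / occasional / elevated / severe,
  cut points 53/120/300 s/day scratching and 7/19/43 min/day licking); an
  alert on any day-over-day rise of one level or more, subject to a
  3.5-wear-day sufficiency rule and a day-9 earliest-alert rule.
* **Attribution** — one-to-one greedy matching of alerts to the first
  clinic visit within 28 days; week-of-lag bins; dermatitis subgroups
  (0 / 1 / 2–5 / 6+ first-period dermatitis-outcome visits); prescription
  flagging and treatment-category classification.
* **Statistics** — 2x2 odds ratios by period, overall and stratified by the
  level at alert time, with log-method confidence intervals,

  OR = (a/b)/(c/d),  SE(ln OR) = sqrt(1/a + 1/b + 1/c + 1/d),
  95% CI = exp(ln OR ± 1.96·SE),

  two-tailed normal p-values, and Haldane–Anscombe correction for zero
  cells.
* **Synthetic cohorts** — a tested generator of dog-day telemetry, visits
  and prescriptions (episodic clustered flares, partial collar wear,
  background visit propensity, a configurable owner-response effect) so the
  whole pipeline runs and is validated with no external data.

The package also ships the published reference counts for this design as
plain-CSV fixtures, so every reported odds ratio, confidence interval and
descriptive fraction can be recomputed exactly from counts.

## Worked example

```r
library(itchalert)

cfg <- cohort_config(n_dogs = 1000, rng_seed = 20190102)
sim <- simulate_cohort(cfg)
res <- analyze_cohort(sim$behavior, sim$visits, sim$prescriptions,
                      period_start = cfg$period_start,
                      period_length_days = cfg$period_length_days)
res
```

```
Alert-visit analysis, two 292 day periods
  period 1: 811 dogs, 7916 alerts (mean 9.8/dog), 621 alert visits (7.84% of alerts)
  period 2: 882 dogs, 9142 alerts (mean 10.4/dog), 1133 alert visits (12.39% of alerts)
  combined OR 1.6618 (95% CI 1.50-1.84)
```

Period 1 is the control arm (alerts computed but invisible to owners),
period 2 the exposure arm. Of the period-2 alerts, 12.39% were followed by
a clinic visit within 28 days against 7.84% in period 1, an odds ratio of
1.66 — the simulated owner-response effect (implied population value 1.64)
recovered by the pipeline. The same run as a batch job, writing every stage
output (cohort CSVs, alerts, matches, subgroups, week bins, odds ratios, a
markdown report and a JSON manifest with per-file checksums):

```r
run_pipeline(cfg, "out/")           # or: cfg path to a YAML config
run_pipeline(out_dir = "out-ref/", mode = "reference")  # published counts only
```

The shipped reference counts reproduce the published comparison exactly:

```r
reference_statistics()$odds_ratios[stratification == "combined"]
#>    stratification  stratum    a     b    c      d odds_ratio   ci_low  ci_high ...
#> 1:       combined combined 6980 86237 5382 108148   1.626435 1.567884 1.687171
```

i.e. an overall odds ratio of 1.6264 (95% CI 1.57–1.69, p < 0.0001), with
4.74% of control-period and 7.49% of exposure-period alerts followed by a
4-week visit.

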