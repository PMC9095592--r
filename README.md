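# mhwtrends

Marine heatwaves (MHWs) — discrete periods of anomalously warm sea-surface
temperature (SST) — restructure coastal ecosystems, and their frequency and
intensity differ by biogeographical region and by season. `mhwtrends` is an
R package for asking, per coastal realm and season, *are marine heatwaves
getting worse, how fast, and since when?* It is aimed at marine ecologists
and climate analysts working with daily gridded SST (e.g. NOAA OISST) and a
pixel-to-realm assignment, and at methodologists who want a fully synthetic,
ground-truthed test bed for the whole detection-to-trend chain.

## What it computes

**Detection.** For each pixel, a fixed-baseline day-of-year climatology is
built from a 30-year window (default 1983–2012): for each day-of-year *d*,
all baseline days within ±5 days of *d* are pooled across years; the
climatological mean μ(d) is the pooled mean and the threshold T(d) the
pooled 90th percentile, both smoothed with a 31-day circular moving
average. An MHW is a run of ≥ 5 consecutive days with SST > T(d); runs
separated by ≤ 2 below-threshold days are joined. Daily intensity is
SST − μ(d). Five metrics are summarised per year and per
hemisphere-dependent season: MHW days, number of events, mean intensity
(°C), maximum intensity (°C), and cumulative intensity (°C·days). Realm
series are pixel-averaged (summed metrics divided by the realm's pixel
count) so realms of different sizes are comparable.

**Trend suite.** Each realm × season × metric stratum's yearly series is
fitted with `mhw_trend()`:

- Mann–Kendall: S = Σ_{i<j} sgn(v_j − v_i), tie-corrected variance, and a
  continuity-corrected normal deviate z with a two-sided p-value;
- Theil–Sen: slope = median of all pairwise slopes (v_j − v_i)/(y_j − y_i),
  intercept = median(v − slope·y), reported per year and per decade;
- Pettitt: U_t = Σ_{i≤t} Σ_{j>t} sgn(v_i − v_j), K = max|U_t|,
  p = min(1, 2·exp(−6K²/(n³ + n²))); the change year is the first year of
  the "after" regime;
- both trend statistics re-fitted before and after the change year, with
  the after/before slope-magnitude ratio;
- a direction call: *increase* if p ≤ α and slope > 0, *decrease* if p ≤ α
  and slope < 0, else *no change* (α = 0.05 by default, uncorrected).

A synthetic generator (`generate_grid()`) produces multi-decade daily SST
with a seasonal harmonic, a piecewise-linear warming trend with an optional
level step at a change year, AR(1) noise, and injectable trapezoidal warm
events — all recorded as ground truth, so every stage can be validated.

## Worked example

One synthetic pixel under the default study conditions (1982–2021, modest
warming that accelerates in 2002), detection, yearly summary, trend fit:

```r
library(mhwtrends)
cfg  <- synth_config()                 # 40 years, AR(1) noise, 2002 break
s    <- generate_series(cfg, pixel_id = "demo")
clim <- compute_climatology(s)         # baseline 1983-2012
ev   <- detect_events(s, clim)
pm   <- summarize_period(s, clim, ev, "year")
fit  <- mhw_trend(pm$mhw_days, pm$year, stratum = "demo:annual:mhw_days")
summary(fit)
```

```
Nonparametric trend suite for stratum 'demo:annual:mhw_days'
  n = 40 years (1982-2021)
  Mann-Kendall: S = 498, z = 5.907, p = 3.474e-09
  Theil-Sen slope: 0.875 per year (8.75 per decade)
  Pettitt: change year 2006, K = 363, p = 1.167e-05
  Direction at alpha = 0.05: increase
  before change year: slope 0/yr, MK p = 0.07418 (n = 24)
  after  change year: slope 3.155/yr, MK p = 0.002506 (n = 16)
```

Read: this pixel gained about 0.9 MHW days per year over the record
(8.75 days/decade), the increase is highly significant, and a rank-based
change point in 2006 separates a flat early regime from a steep late one
(3.2 days/year after). Note the change point trails the 2002 slope break —
with a fixed baseline, day counts respond progressively to a trend change,
so Pettitt's median-shift estimate lags a pure slope break by a few years.

The full pipeline (grid → detection → realm/season strata → classified
trends) is one call:

```r
counts <- setNames(rep(2L, 12), meow_realms()$realm)
res <- run_pipeline(run_config(synthetic = list(n_pixels_per_realm = counts),
                               out_dir = "out", seed = 1))
res$direction_summary
#   pct_increase pct_decrease pct_no_change n_strata
# 1         72.5            0          27.5      240
```

240 strata = 12 realms × 4 seasons × 5 metrics; global annual and seasonal
series are fitted alongside. Outputs land in `out/` as tidy CSVs
(`events.csv`, `metric_series.csv`, `strata_results.csv`,
`global_results.csv`, `direction_summary.csv`) plus a JSON run manifest;
re-running the same configuration reproduces them byte-identically.

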