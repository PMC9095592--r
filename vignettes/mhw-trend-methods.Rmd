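---
title: "Methods: marine heatwave detection and trend classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: marine heatwave detection and trend classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhwtrends)
```

## The analysis in one paragraph

`mhwtrends` takes multi-decade daily sea-surface temperature (SST) for a
set of pixels, each assigned to a coastal biogeographical realm and a
hemisphere, and answers whether five marine-heatwave (MHW) metrics — days,
events, mean, maximum and cumulative intensity — are trending up or down in
every realm × season × metric stratum. Detection uses a fixed-baseline
day-of-year percentile climatology; inference uses rank-based statistics
throughout (Mann–Kendall, Theil–Sen, Pettitt), which assume only
exchangeability under the null, not normality or linear-model residual
structure. The design deliberately mirrors the common practice of
large-scale coastal MHW assessments: a fixed 30-year climatology (not a
shifting baseline), per-stratum tests without multiple-testing correction,
and pixel-averaged realm series so differently sized realms are comparable.

## Detection model and its assumptions

For pixel SST series `x(t)`:

1. **Climatology.** For each day-of-year slot `d` (366 slots; see leap-day
   handling below), pool all baseline observations within ±`w` days of `d`
   across all baseline years (`w = 5`, an 11-day window), take the pooled
   mean `mu(d)` and pooled `q`-th percentile `T(d)` (`q = 90`), then smooth
   both curves with a 31-day circular moving average. The defaults are the
   Hobday-style definition's standard parameters; the baseline window
   defaults to 1983-01-01..2012-12-31.
2. **Events.** Days with `x(t) > T(d(t))` (strictly; a tie does not flag)
   form candidate runs; runs of ≥ 5 days are events; events separated by
   ≤ 2 below-threshold days are joined, the gap days counting towards
   duration and metrics. Daily intensity is always `x(t) − mu(d(t))`: the
   anomaly relative to the seasonally varying mean, not the threshold.
3. **Period metrics.** Per calendar year, or per hemisphere-dependent
   season: MHW days, event count, mean / maximum / cumulative intensity of
   event days in the period.

The key assumption of the fixed baseline is that "heatwave" keeps its
1983–2012 meaning throughout: under sustained warming, later years exceed
the fixed threshold more often, which is precisely the signal the trend
suite quantifies (a shifting baseline would remove it).

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `percentile` | 90 | — | standard MHW threshold definition |
| `window_half_width` | 5 | days | 11-day pooling window of the standard definition |
| `smooth_width` | 31 | days | standard circular smoother; attenuates a 4 °C annual harmonic by < 0.1 °C |
| `min_duration` | 5 | days | an MHW is a prolonged event, not a hot spell |
| `max_gap` | 2 | days | brief dips don't end an ecological heat event |
| `baseline` | 1983–2012 | — | 30-year fixed climatological reference |
| `alpha` | 0.05 | — | two-sided, per stratum, uncorrected (see below) |

α is deliberately uncorrected across the 240 strata: the strata are
reported individually, as is standard in this literature; a
family-wise-corrected variant is a one-line change (`alpha =`) for users
who want it.

## Seasonal and realm aggregation

Seasons are the traditional 3-month blocks — northern hemisphere:
June–August summer, September–November autumn, December–February winter,
March–May spring — with months mirrored in the south. Two conventions were
genuinely open and are fixed as follows:

- **December's year label.** December belongs to the season year of the
  following January (December 2000 is winter 2001 in the north, summer 2001
  in the south). This keeps every season one contiguous 3-month run. The
  first and last partial seasons of a record are dropped from trend series.
- **Equator pixels.** Latitude 0 uses the northern convention (a strict
  `> 0 / < 0` rule would leave it unassigned).
- **Season-boundary events.** An event spanning a boundary is partitioned
  by day: each period receives the days, cumulative intensity, and its own
  mean/max over the event days inside it, while the *event count* goes to
  the period containing the start date. This conserves day totals exactly
  (tested) and never double-counts events.
- **Per-period mean intensity** is the day-weighted mean over all event
  days in the period (not a mean of per-event means); with partitioned
  events the day-weighted form is the only one that aggregates
  consistently.

Realm aggregation divides summed metrics (days, events, cumulative
intensity) by the realm's total pixel count — including event-free pixels —
making realms of different sizes directly comparable. Mean and maximum
intensity are instead averaged over event-bearing pixels only: imputing 0
for an event-free pixel would assert "an event at exactly the
climatological mean", which is not a neutral value. No area weighting is
applied (pixel areas vary with latitude); realm series are pixel counts'
averages, as is conventional for this analysis.

## The trend suite

All three tests are rank-based. For a stratum's yearly values `v` at years
`y` (years, not indices, are the covariate, so missing years do not distort
slopes; years with missing values are dropped entirely):

- **Mann–Kendall**: `S = Σ_{i<j} sgn(v_j − v_i)`;
  `var(S) = [n(n−1)(2n+5) − Σ_g t_g(t_g−1)(2t_g+5)]/18` over tie groups;
  `z = (S∓1)/sqrt(var S)` with continuity correction; two-sided normal
  p-value. An all-tied series (var = 0) reports z = 0, p = 1.
- **Theil–Sen**: slope = median pairwise slope; intercept =
  `median(v − slope·y)` (Conover form — only used for trendlines);
  decadal slope = 10 × yearly slope.
- **Pettitt**: `U_t = Σ_{i≤t}Σ_{j>t} sgn(v_i − v_j)`, `K = max|U_t|`,
  `p = min(1, 2 exp(−6K²/(n³+n²)))`. The approximation can exceed 1 for
  small K; it is clamped. Ties contribute 0; argmax ties resolve to the
  earliest index, making output deterministic.
- **Segmentation**: the change year (year at index `t* + 1`) starts the
  "after" regime — `before: y < change year`, `after: y ≥ change year`.
  Segments with fewer than 3 years are flagged unavailable; the
  after/before ratio compares slope magnitudes and is undefined when the
  before slope is 0.
- **Direction**: increase / decrease / no-change from the *full-series*
  Mann–Kendall p and Theil–Sen slope sign at level α.

`mhw_trend()` bundles all of this into one fitted object with
`print`/`summary`/`coef`/`predict`/`residuals`/`plot` methods;
`fit_strata()` maps it over a strata table.

## What the synthetic generator emulates — and what it does not

`generate_series()` produces
`SST(t) = mean + A·sin(2π·doy(t)/365.25 + φ) + trend(t) + AR(1)`,
with a piecewise-linear trend (slope change at the change year, continuous
at the joint, plus an optional level step) and AR(1) daily residuals.
Defaults describe a realistic mid-latitude coastal pixel over the 1982–2021
study span: mean 14 °C, amplitude 4 °C, warming 0.01 °C/yr accelerating to
0.03 °C/yr at 2002 (change points in coastal MHW records cluster around the
late 1990s–mid 2000s), AR coefficient 0.7 and innovation SD 0.4 °C (daily
SST anomalies are strongly persistent; the implied stationary SD is
≈ 0.56 °C). Noise is AR(1) rather than white because downstream stochastic
checks must be calibrated against realistic persistence. Per-pixel seeds
are a deterministic hash of (master seed, pixel id), so grids are
extensible without reshuffling existing pixels. Discrete warm events are
injected as trapezoids (linear ramps around a plateau) and recorded as
ground truth.

Not emulated: spatial covariance between pixels (pixels are independent),
sea-ice masking, satellite retrieval error structure, and skewness of real
SST anomaly distributions. Passing tests therefore demonstrate correctness
of the *machinery* (detection arithmetic, aggregation bookkeeping, test
statistics, classification logic) and statistical calibration under
persistent Gaussian noise — not that any particular real-world realm's
trend is reproduced.

## Numerical choices and degenerate inputs

- **Leap days.** Day-of-year uses 366 slots with 1 March always slot 61.
  The 29 Feb climatology is the average of the smoothed 28 Feb and 1 Mar
  values; 29 Feb observations still contribute to neighbouring slots'
  pooling windows. This matches common reference implementations and can
  move an event boundary by at most one day.
- **Percentile.** Pooled percentiles use R's default interpolation
  (type 7); the test oracle re-derives it independently by sorting.
- **Missing data.** A missing day is never flagged, breaks a run, and
  blocks gap-joining across it; baselines with > 10 % missing days are
  rejected (gridded OISST-like input is gap-free; missingness in tests is
  always explicit).
- **Threshold sanity.** If the smoothed threshold falls below the smoothed
  mean — impossible for real SST, possible for adversarial synthetic input —
  the climatology errors out rather than producing negative-intensity
  "events".
- **Pettitt p-clamp.** Reported p is capped at 1, matching standard
  practice for the exponential approximation.

## Problem sizes

The test suite exercises: exhaustive oracle equivalence on all `{0,1,2}`
series of length ≤ 8 (13 000 series against brute-force pairwise
enumeration); exhaustive detector/oracle comparison over all 4 096 flag
patterns of length 12 plus 300 random length-20 patterns; 10 000 iid
Gaussian series (n = 40) for the type-I rate; 1 000 AR(1) replicates for
Theil–Sen recovery and 500 for Pettitt step localisation; and a full
seasonal pipeline on a 12-realm × 5-pixel, 40-year grid (240 strata). The
acceptance script runs the same pipeline at 2 pixels per realm. These sizes
give Monte-Carlo error well inside the asserted bands while keeping a full
run in the low minutes on one core.

## Known limitations

- The Mann–Kendall and Pettitt p-values assume serial independence of the
  *yearly* values; yearly MHW metrics retain mild autocorrelation under
  persistent daily noise, so nominal levels are approximate (the type-I
  calibration is performed on iid series, as is standard). Pre-whitened MK
  variants are intentionally out of scope.
- Pettitt locates *shifts in central tendency*: it dates a pure slope
  change only loosely (typically a few years late), while a level step is
  located within a year or two. Both regimes are testable via the
  generator's `trend_after` and `level_step`.
- No MHW category scheme (Moderate/Strong/...), no cold-spell detection,
  no detrended or shifting baselines, no Sen-slope confidence intervals.
- NetCDF I/O is not provided; the interchange formats are the long-format
  daily SST CSV, the realm-table CSV, and the JSON truth sidecar.
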