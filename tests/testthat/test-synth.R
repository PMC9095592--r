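# Synthetic SST generator: closed-form checks, AR(1) noise calibration,
# event injection, grid construction and truth round-trip.

test_that("noise-free, trend-free series is the pure harmonic", {
  cfg <- synth_config("2000-01-01", "2009-12-31", mean_level = 12,
                      seasonal_amplitude = 3, noise_sd = 0,
                      trend_before = 0, trend_after = 0, change_year = NA)
  s <- generate_series(cfg)
  doy <- doy_slot(s$date)
  expected <- 12 + 3 * sin(2 * pi * doy / 365.25)
  expect_equal(s$sst, expected)
  # max - min = 2 * amplitude (up to daily discretisation of the harmonic)
  expect_equal(diff(range(s$sst)), 2 * 3, tolerance = 1e-4)
})

test_that("constant linear trend accumulates as slope x elapsed years", {
  cfg <- synth_config("1982-01-01", "2021-12-31", noise_sd = 0,
                      trend_before = 0.02, trend_after = 0.02,
                      change_year = NA)
  s <- generate_series(cfg)
  jan1 <- s$sst[format(s$date, "%m-%d") == "01-01"]
  expect_length(jan1, 40)
  expect_equal(tail(jan1, 1) - jan1[1], 39 * 0.02, tolerance = 1e-3)
})

test_that("piecewise trend is continuous at the change year and bends after", {
  cfg <- synth_config("1990-01-01", "2019-12-31", noise_sd = 0,
                      seasonal_amplitude = 0, trend_before = 0.01,
                      trend_after = 0.05, change_year = 2005)
  s <- generate_series(cfg)
  expect_false(any(abs(diff(s$sst)) > 0.05 / 300))  # no jump anywhere
  jan1 <- s$sst[format(s$date, "%m-%d") == "01-01"]
  yrs <- 1990:2019
  before <- diff(jan1[yrs < 2005])
  after <- diff(jan1[yrs > 2005])
  expect_equal(mean(before), 0.01, tolerance = 1e-3)
  expect_equal(mean(after), 0.05, tolerance = 1e-3)
})

test_that("level step shifts the after-regime by the configured amount", {
  base <- synth_config("1990-01-01", "2009-12-31", noise_sd = 0,
                       seasonal_amplitude = 0, trend_before = 0,
                       trend_after = 0, change_year = 2000, level_step = 0)
  stepped <- base; stepped$level_step <- 1.5
  s0 <- generate_series(base); s1 <- generate_series(stepped)
  d <- s1$sst - s0$sst
  expect_equal(unique(d[s0$date < as.Date("2000-01-01")]), 0)
  expect_equal(unique(d[s0$date >= as.Date("2000-01-01")]), 1.5)
})

test_that("AR(1) residual variance matches the stationary value", {
  cfg <- synth_config("1990-01-01", "2019-12-31", mean_level = 0,
                      seasonal_amplitude = 0, trend_before = 0,
                      trend_after = 0, change_year = NA,
                      ar_coefficient = 0.5, noise_sd = 1, rng_seed = 7)
  s <- generate_series(cfg)
  expect_gt(length(s$sst), 10000)
  expect_equal(var(s$sst), 1 / (1 - 0.25), tolerance = 0.05)
  expect_lt(abs(mean(s$sst)), 0.1)  # residual mean ~ 0
})

test_that("identical config and seed give bit-identical output", {
  cfg <- synth_config("2000-01-01", "2004-12-31", rng_seed = 99)
  expect_identical(generate_series(cfg)$sst, generate_series(cfg)$sst)
})

test_that("config validation rejects bad spans, AR and noise values", {
  expect_error(synth_config("2000-01-01", "2001-06-30"), "2 years")
  expect_error(synth_config(ar_coefficient = 1), "ar_coefficient")
  expect_error(synth_config(noise_sd = -1), "noise_sd")
})

test_that("event injection is the identity for empty or zero-amplitude events", {
  cfg <- synth_config("2000-01-01", "2004-12-31")
  s <- generate_series(cfg, "px1")
  expect_equal(inject_events(s, NULL)$sst, s$sst)
  ev0 <- injected_event("px1", "2001-06-01", 10, 0)
  expect_equal(inject_events(s, ev0)$sst, s$sst)
})

test_that("a ramp-free event adds exactly its amplitude on its plateau days", {
  cfg <- synth_config("2000-01-01", "2004-12-31", noise_sd = 0)
  s <- generate_series(cfg, "px1")
  ev <- injected_event("px1", "2001-06-01", 10, 3, ramp_days = 0)
  out <- inject_events(s, ev)
  d <- out$sst - s$sst
  hot <- out$date >= as.Date("2001-06-01") & out$date <= as.Date("2001-06-10")
  expect_equal(d[hot], rep(3, 10))
  expect_equal(d[!hot], rep(0, sum(!hot)))
  expect_equal(s$sst, generate_series(cfg, "px1")$sst)  # input unmodified
})

test_that("ramped events form a trapezoid and out-of-span events error", {
  cfg <- synth_config("2000-01-01", "2004-12-31", noise_sd = 0)
  s <- generate_series(cfg, "px1")
  ev <- injected_event("px1", "2001-06-01", 4, 2, ramp_days = 3)
  d <- inject_events(s, ev)$sst - s$sst
  i0 <- which(s$date == as.Date("2001-06-01"))
  expect_equal(d[(i0 - 3):(i0 + 6)],
               2 * c(1 / 4, 2 / 4, 3 / 4, 1, 1, 1, 1, 3 / 4, 2 / 4, 1 / 4))
  bad <- injected_event("px1", "2004-12-30", 10, 3)
  expect_error(inject_events(s, bad), "span")
})

test_that("grid places one series per pixel with realm labels and hemispheres", {
  counts <- setNames(rep(1L, 12), meow_realms()$realm)
  cfg <- synth_config("2000-01-01", "2004-12-31")
  g <- generate_grid(counts, cfg)
  expect_equal(nrow(g$pixels), 12)
  expect_setequal(g$pixels$realm, meow_realms()$realm)
  expect_equal(g$pixels$hemisphere,
               ifelse(g$pixels$latitude >= 0, "north", "south"))
  expect_length(g$series, 12)
})

test_that("pixels get distinct noise but stable per-pixel seeds", {
  counts <- c(A = 2L)
  cfg <- synth_config("2000-01-01", "2004-12-31", rng_seed = 5)
  g <- generate_grid(counts, cfg)
  s1 <- g$series[[1]]$sst; s2 <- g$series[[2]]$sst
  expect_false(identical(s1, s2))
  # extending the grid must not reshuffle existing pixels
  g2 <- generate_grid(c(A = 3L), cfg)
  expect_identical(g2$series[["a_01"]]$sst, s1)
  expect_identical(g2$series[["a_02"]]$sst, s2)
})

test_that("realm overrides apply only to that realm", {
  counts <- c(A = 1L, B = 1L)
  cfg <- synth_config("1990-01-01", "2019-12-31", noise_sd = 0,
                      trend_before = 0, trend_after = 0, change_year = NA)
  g <- generate_grid(counts, cfg,
                     per_realm_overrides = list(B = list(trend_after = 0.5,
                                                         trend_before = 0.5)))
  trend_of <- function(s) {
    jan1 <- s$sst[format(s$date, "%m-%d") == "01-01"]
    (tail(jan1, 1) - jan1[1]) / 29
  }
  expect_equal(trend_of(g$series[["a_01"]]), 0, tolerance = 1e-9)
  expect_equal(trend_of(g$series[["b_01"]]), 0.5, tolerance = 1e-3)
})

test_that("SST CSV and truth sidecar round-trip a grid unchanged", {
  counts <- c(A = 1L, B = 2L)
  cfg <- synth_config("2000-01-01", "2004-12-31", rng_seed = 3)
  ev <- injected_event("a_01", "2002-06-01", 10, 3, ramp_days = 2)
  g <- generate_grid(counts, cfg, events = ev)
  tmp <- withr::local_tempdir()
  write_sst_csv(g, file.path(tmp, "sst.csv"))
  write_realm_csv(g$pixels, file.path(tmp, "realms.csv"))
  write_truth_json(g, file.path(tmp, "truth.json"))
  series2 <- read_sst_csv(file.path(tmp, "sst.csv"))
  expect_setequal(names(series2), names(g$series))
  for (pid in names(series2)) {
    expect_equal(series2[[pid]]$sst, g$series[[pid]]$sst, tolerance = 1e-12)
    expect_equal(series2[[pid]]$date, g$series[[pid]]$date)
  }
  truth <- read_truth_json(file.path(tmp, "truth.json"))
  expect_equal(truth$config$rng_seed, 3)
  expect_equal(as.data.frame(truth$events), as.data.frame(ev))
  realms2 <- read_realm_csv(file.path(tmp, "realms.csv"))
  expect_equal(realms2$realm, g$pixels$realm)
})
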