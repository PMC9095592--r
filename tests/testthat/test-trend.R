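# Trend suite: worked statistics, brute-force pairwise-enumeration oracles
# (exhaustive on short integer series), invariances, and the fitted-object
# interface.

test_that("Mann-Kendall reproduces the worked monotone example", {
  mk <- mann_kendall(c(1, 2, 3, 4, 5))
  expect_equal(mk$S, 10)                       # all 10 pairs concordant
  expect_equal(mk$var_S, 50 / 3, tolerance = 1e-12)
  expect_equal(mk$z, 9 / sqrt(50 / 3), tolerance = 1e-12)
  expect_equal(mk$p, 2 * pnorm(-9 / sqrt(50 / 3)), tolerance = 1e-12)
  expect_equal(round(mk$z, 3), 2.205)
  # antisymmetry
  expect_equal(mann_kendall(c(5, 4, 3, 2, 1))$S, -10)
})

test_that("Mann-Kendall S agrees with Kendall's tau from cor.test", {
  set.seed(2)
  for (r in 1:20) {
    v <- rnorm(15)
    ct <- suppressWarnings(cor.test(seq_along(v), v, method = "kendall"))
    n <- length(v)
    expect_equal(mann_kendall(v)$S, unname(ct$estimate) * n * (n - 1) / 2,
                 tolerance = 1e-8)
  }
})

test_that("tied and degenerate series are handled", {
  mk <- mann_kendall(c(2, 2, 2, 2))
  expect_equal(mk$var_S, 0)
  expect_equal(mk$z, 0)
  expect_equal(mk$p, 1)
  # tie correction: duplicated values lower var_S
  v <- c(1, 2, 2, 3, 4)
  full <- 5 * 4 * 15 / 18
  expect_equal(mann_kendall(v)$var_S, (5 * 4 * 15 - 2 * 1 * 9) / 18)
  expect_lt(mann_kendall(v)$var_S, full)
  expect_error(mann_kendall(c(1, 2)), "at least 3")
})

test_that("Theil-Sen slope matches enumerated pairwise slopes", {
  s <- sen_slope(c(0, 0, 10), 1:3)
  expect_equal(s$slope, 5)  # pairwise slopes {0, 5, 10}
  # exact line recovers slope and intercept
  yrs <- c(1990, 1993, 1994, 1999, 2005)
  s2 <- sen_slope(2 * yrs + 7, yrs)
  expect_equal(s2$slope, 2)
  expect_equal(s2$intercept, 7)
  expect_equal(s2$slope_per_decade, 20)
  # shift equivariance
  v <- c(3, 1, 4, 1, 5)
  s3 <- sen_slope(v, 1:5); s4 <- sen_slope(v + 11, 1:5)
  expect_equal(s4$slope, s3$slope)
  expect_equal(s4$intercept, s3$intercept + 11)
  expect_error(sen_slope(c(1), 1), "at least 2")
})

test_that("Pettitt reproduces the worked step example and symmetry", {
  pt <- pettitt(c(0, 0, 0, 0, 10, 10, 10, 10), 1:8)
  expect_equal(pt$K, 16)
  expect_equal(pt$t_star, 4)
  expect_equal(pt$change_year, 5)
  expect_equal(pt$p, 2 * exp(-6 * 256 / (512 + 64)), tolerance = 1e-12)
  expect_equal(round(pt$p, 3), 0.139)
  # falling step has identical K and p
  pt2 <- pettitt(c(10, 10, 10, 10, 0, 0, 0, 0), 1:8)
  expect_equal(pt2$K, pt$K)
  expect_equal(pt2$p, pt$p)
  # constant series: degenerate, p clamped to 1
  pt3 <- pettitt(rep(1, 6), 1:6)
  expect_equal(pt3$K, 0)
  expect_equal(pt3$p, 1)
  expect_error(pettitt(c(1, 2, 3), 1:3), "at least 4")
})

test_that("S, U_t and Sen slope match brute force on all short {0,1,2} series", {
  for (n in 3:8) {
    grid <- as.matrix(expand.grid(rep(list(0:2), n)))
    ok <- apply(grid, 1, function(v) {
      v <- as.numeric(v)
      if (mann_kendall(v)$S != oracle_mk_S(v)) return(FALSE)
      if (!isTRUE(all.equal(sen_slope(v, 1:n)$slope,
                            oracle_sen_slope(v, 1:n)))) return(FALSE)
      if (n >= 4) {
        pt <- pettitt(v, 1:n)
        U <- oracle_pettitt_U(v)
        if (!identical(as.numeric(pt$U), as.numeric(U))) return(FALSE)
        if (pt$K != max(abs(U))) return(FALSE)
        if (pt$t_star != which.max(abs(U))) return(FALSE)
      }
      TRUE
    })
    expect_true(all(ok), label = sprintf("oracle equivalence at n = %d", n))
  }
})

test_that("location shifts leave MK p and Pettitt K unchanged", {
  set.seed(5)
  for (r in 1:10) {
    v <- rnorm(20)
    expect_equal(mann_kendall(v + 100)$p, mann_kendall(v)$p)
    expect_equal(pettitt(v + 100, 1:20)$K, pettitt(v, 1:20)$K)
    expect_equal(pettitt(-v, 1:20)$K, pettitt(v, 1:20)$K)  # sign flip
  }
})

test_that("years (not indices) are the Sen time covariate", {
  yrs <- c(2000:2004, 2010:2014)  # a 5-year hole
  v <- 0.5 * yrs + 3
  expect_equal(sen_slope(v, yrs)$slope, 0.5)
})

test_that("split_trends recovers piecewise slopes and their ratio", {
  yrs <- 1981:2020
  v <- ifelse(yrs < 2001, 0.1 * (yrs - 1980), 0.1 * 20 + 1.0 * (yrs - 2000))
  sp <- split_trends(v, yrs, 2001)
  expect_equal(sp$before$sen$slope, 0.1, tolerance = 1e-9)
  expect_equal(sp$after$sen$slope, 1.0, tolerance = 1e-9)
  expect_equal(sp$slope_ratio, 10, tolerance = 1e-9)
  # identical slopes give ratio 1
  sp2 <- split_trends(0.3 * yrs, yrs, 2001)
  expect_equal(sp2$slope_ratio, 1)
  # segment boundary: change year belongs to the after regime
  expect_equal(sp$after$mk$n, 20)
  expect_equal(sp$before$mk$n, 20)
  # short segments are flagged unavailable
  sp3 <- split_trends(v, yrs, 1983)
  expect_null(sp3$before)
  expect_true(is.na(sp3$slope_ratio))
  expect_error(split_trends(v, yrs, 1975), "span")
})

test_that("directions classify by significance and slope sign", {
  expect_equal(classify_direction(0.01, 1.2), "increase")
  expect_equal(classify_direction(0.50, 1.2), "no_change")
  expect_equal(classify_direction(0.01, -0.3), "decrease")
  expect_equal(classify_direction(0.04, 0.3, alpha = 0.01), "no_change")
  expect_equal(classify_direction(0.01, 0), "no_change")
})

test_that("direction shares are percentages that sum to 100", {
  dirs <- c(rep("increase", 168), rep("decrease", 12), rep("no_change", 60))
  s <- summarize_directions(dirs)
  expect_equal(s$pct_increase, 70)
  expect_equal(s$pct_decrease, 5)
  expect_equal(s$pct_no_change, 25)
  expect_equal(summarize_directions(rep("increase", 7)),
               list(pct_increase = 100, pct_decrease = 0, pct_no_change = 0))
  s3 <- summarize_directions(c("increase", "decrease", "no_change"))
  expect_equal(s3$pct_increase, 100 / 3, tolerance = 1e-9)
  expect_error(summarize_directions(character()), "empty")
})

test_that("mhw_trend bundles the suite and its methods are coherent", {
  yrs <- 1982:2021
  set.seed(9)
  v <- ifelse(yrs < 2002, 5, 9) + rnorm(40, sd = 0.5)
  fit <- mhw_trend(v, yrs, stratum = "toy:annual:mhw_days")
  expect_s3_class(fit, "mhw_trend")
  expect_equal(fit$direction, "increase")
  expect_equal(fit$pettitt$change_year, 2002)
  expect_equal(unname(coef(fit)),
               c(fit$sen$intercept, fit$sen$slope))
  expect_equal(predict(fit), fit$sen$intercept + fit$sen$slope * yrs)
  expect_equal(residuals(fit), v - predict(fit))
  expect_output(print(fit), "Mann-Kendall")
  expect_output(summary(fit), "after")
  # missing years are dropped entirely
  v2 <- v; v2[c(5, 17)] <- NA
  fit2 <- mhw_trend(v2, yrs)
  expect_equal(fit2$mk$n, 38)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("fit_strata returns one tidy row per stratum", {
  yrs <- 2000:2019
  strata <- do.call(rbind, lapply(c("up", "flat"), function(nm) {
    data.frame(scope = "realm", stratum = paste0("A:", nm), realm = "A",
               season = "annual", metric = nm, year = yrs,
               value = if (nm == "up") yrs - 1999 else rep(c(1, 2), 10),
               n_pixels = 1)
  }))
  res <- fit_strata(strata, min_years = 5)
  expect_equal(nrow(res), 2)
  expect_equal(res$direction[res$metric == "up"], "increase")
  expect_equal(res$direction[res$metric == "flat"], "no_change")
  expect_named(attr(res, "fits"), c("A:up", "A:flat"))
  w <- capture_warnings(fit_strata(strata[strata$year < 2008, ],
                                   min_years = 10))
  expect_true(any(grepl("< 10", w)))
})
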