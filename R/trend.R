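# Nonparametric trend and change-point suite for yearly metric series:
# Mann-Kendall test (tie-corrected variance, continuity correction),
# Theil-Sen slope (median of pairwise slopes, Conover intercept), Pettitt
# change-point test (rank-based, with the standard exponential significance
# approximation clamped at 1), and before/after trend re-fitting around the
# detected change year.

#' Mann-Kendall trend test
#'
#' S is the number of concordant minus discordant pairs; its variance uses
#' the tie correction, and the normal deviate z applies the +/- 1 continuity
#' correction. When every value is tied (var_S = 0) the test is degenerate
#' and reported as z = 0, p = 1.
#'
#' @param values numeric vector (NA values removed; at least 3 non-missing).
#' @return list with `S`, `var_S`, `z`, `p` (two-sided) and `n`.
#' @export
mann_kendall <- function(values) {
  v <- values[!is.na(values)]
  n <- length(v)
  if (n < 3) stop("mann_kendall needs at least 3 non-missing values")
  d <- sign(outer(v, v, "-"))
  S <- sum(d[lower.tri(d)])
  ties <- table(v)
  ties <- ties[ties > 1]
  var_S <- (n * (n - 1) * (2 * n + 5) -
            sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  if (var_S == 0) {
    z <- 0; p <- 1
  } else if (S > 0) {
    z <- (S - 1) / sqrt(var_S); p <- 2 * pnorm(-abs(z))
  } else if (S < 0) {
    z <- (S + 1) / sqrt(var_S); p <- 2 * pnorm(-abs(z))
  } else {
    z <- 0; p <- 1
  }
  list(S = S, var_S = var_S, z = z, p = min(1, p), n = n)
}

#' Theil-Sen slope and intercept
#'
#' Slope is the median of all pairwise slopes (v_j - v_i)/(year_j - year_i),
#' i < j; the intercept is median(v - slope * year). Years (not indices) are
#' the time covariate, so missing years do not distort the slope.
#'
#' @param values numeric vector.
#' @param years strictly increasing numeric vector, same length.
#' @return list with `slope` (units/year), `intercept`,
#'   `slope_per_decade` (= 10 * slope) and `n`.
#' @export
sen_slope <- function(values, years) {
  keep <- !is.na(values)
  v <- values[keep]; yr <- years[keep]
  n <- length(v)
  if (n < 2) stop("sen_slope needs at least 2 non-missing values")
  if (is.unsorted(yr, strictly = TRUE)) stop("years must be strictly increasing")
  ij <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)  # (row i > col j)
  slopes <- (v[ij[, 1]] - v[ij[, 2]]) / (yr[ij[, 1]] - yr[ij[, 2]])
  slope <- median(slopes)
  list(slope = slope, intercept = median(v - slope * yr),
       slope_per_decade = 10 * slope, n = n)
}

#' Pettitt change-point test
#'
#' U_t sums sgn(v_i - v_j) over all pairs that straddle a candidate split
#' after index t; the change point maximises |U_t| (earliest index on ties).
#' Significance uses the standard approximation
#' p = 2 exp(-6 K^2 / (n^3 + n^2)), clamped at 1 (the approximation can
#' exceed 1 for small K). The change year is the first year of the "after"
#' segment.
#'
#' @param values numeric vector (at least 4 non-missing).
#' @param years years aligned with `values`.
#' @return `pettitt_test` list: `U` (U_t for t = 1..n-1), `K`, `t_star`,
#'   `change_year`, `p`, `n`.
#' @export
pettitt <- function(values, years) {
  keep <- !is.na(values)
  v <- values[keep]; yr <- years[keep]
  n <- length(v)
  if (n < 4) stop("pettitt needs at least 4 non-missing values")
  d <- sign(outer(v, v, "-"))        # d[i, j] = sgn(v_i - v_j)
  rowcontrib <- rowSums(d)
  # U_t = U_{t-1} + sum_j sgn(v_t - v_j)
  U <- cumsum(rowcontrib)[1:(n - 1)]
  K <- max(abs(U))
  t_star <- which.max(abs(U))        # earliest argmax
  p <- min(1, 2 * exp(-6 * K^2 / (n^3 + n^2)))
  out <- list(U = U, K = K, t_star = t_star,
              change_year = yr[t_star + 1L], p = p, n = n)
  class(out) <- "pettitt_test"
  out
}

#' @export
print.pettitt_test <- function(x, ...) {
  cat(sprintf("Pettitt change-point test: K = %g, change year = %s, p = %.4g (n = %d)\n",
              x$K, format(x$change_year), x$p, x$n))
  invisible(x)
}

#' Re-fit trends before and after a change year
#'
#' The "after" segment starts at the change year (the change year belongs to
#' the new regime); the "before" segment is all earlier years. Each segment
#' with at least 3 observations gets its own Mann-Kendall test and Theil-Sen
#' slope; shorter segments are flagged unavailable (NULL).
#'
#' @param values,years the full series.
#' @param change_year first year of the after segment; must lie strictly
#'   inside the span of `years`.
#' @return list with `before`, `after` (each a list with `mk` and `sen`, or
#'   NULL) and `slope_ratio` = |after slope| / |before slope| (NA when
#'   either segment is unavailable or the before slope is 0).
#' @export
split_trends <- function(values, years, change_year) {
  keep <- !is.na(values)
  v <- values[keep]; yr <- years[keep]
  if (change_year <= min(yr) || change_year > max(yr)) {
    stop("change_year outside the series span")
  }
  fit_segment <- function(vv, yy) {
    if (length(vv) < 3) return(NULL)
    list(mk = mann_kendall(vv), sen = sen_slope(vv, yy))
  }
  before <- fit_segment(v[yr < change_year], yr[yr < change_year])
  after <- fit_segment(v[yr >= change_year], yr[yr >= change_year])
  ratio <- if (!is.null(before) && !is.null(after) &&
               before$sen$slope != 0) {
    abs(after$sen$slope) / abs(before$sen$slope)
  } else NA_real_
  list(before = before, after = after, slope_ratio = ratio)
}

#' Classify a trend direction
#'
#' @param p Mann-Kendall two-sided p-value.
#' @param slope Theil-Sen slope.
#' @param alpha significance level (default 0.05).
#' @return `"increase"`, `"decrease"`, or `"no_change"`.
#' @export
classify_direction <- function(p, slope, alpha = 0.05) {
  if (is.na(p) || is.na(slope)) return("no_change")
  if (p <= alpha && slope > 0) "increase"
  else if (p <= alpha && slope < 0) "decrease"
  else "no_change"
}

#' Share of increasing / decreasing / unchanged strata
#'
#' @param directions character vector of [classify_direction()] outputs (or
#'   a list of `mhw_trend` objects).
#' @return list with `pct_increase`, `pct_decrease`, `pct_no_change`
#'   (percentages of the input, summing to 100 within rounding).
#' @export
summarize_directions <- function(directions) {
  if (is.list(directions) && length(directions) > 0 &&
      inherits(directions[[1]], "mhw_trend")) {
    directions <- vapply(directions, function(x) x$direction, character(1))
  }
  n <- length(directions)
  if (n == 0) stop("empty direction list")
  list(pct_increase = 100 * sum(directions == "increase") / n,
       pct_decrease = 100 * sum(directions == "decrease") / n,
       pct_no_change = 100 * sum(directions == "no_change") / n)
}

#' Fit the full trend suite to one yearly series
#'
#' The central fitting function: given one stratum's yearly metric values it
#' runs the Mann-Kendall test and Theil-Sen slope on the full series, the
#' Pettitt change-point test, re-fits both trend statistics before and after
#' the detected change year, and classifies the stratum as increasing,
#' decreasing or unchanged at level `alpha` (full-series Mann-Kendall p and
#' Theil-Sen slope sign). Years with missing values are dropped entirely.
#'
#' @param values yearly metric values (NA allowed).
#' @param years corresponding years; defaults to `seq_along(values)`.
#' @param alpha two-sided significance level (default 0.05, uncorrected
#'   across strata).
#' @param stratum optional label carried on the object.
#' @return an object of class `mhw_trend` with components `mk`, `sen`,
#'   `pettitt`, `before`, `after`, `slope_ratio`, `direction`, plus the
#'   (non-missing) data. Methods: [print.mhw_trend()], [summary.mhw_trend()],
#'   `coef`, `predict`, `residuals`, `plot`.
#' @examples
#' fit <- mhw_trend(c(1, 2, 1.5, 3, 4, 3.5, 9, 10, 11, 12),
#'                  years = 2001:2010)
#' fit$direction
#' coef(fit)
#' @export
mhw_trend <- function(values, years = seq_along(values), alpha = 0.05,
                      stratum = NULL) {
  stopifnot(length(values) == length(years))
  ord <- order(years)
  values <- values[ord]; years <- years[ord]
  keep <- !is.na(values)
  v <- values[keep]; yr <- years[keep]
  if (length(v) < 3) stop("mhw_trend needs at least 3 non-missing values")
  mk <- mann_kendall(v)
  sen <- sen_slope(v, yr)
  pt <- if (length(v) >= 4) pettitt(v, yr) else NULL
  split <- if (!is.null(pt)) {
    split_trends(v, yr, pt$change_year)
  } else list(before = NULL, after = NULL, slope_ratio = NA_real_)
  out <- list(values = v, years = yr, alpha = alpha, stratum = stratum,
              mk = mk, sen = sen, pettitt = pt,
              before = split$before, after = split$after,
              slope_ratio = split$slope_ratio,
              direction = classify_direction(mk$p, sen$slope, alpha))
  class(out) <- "mhw_trend"
  out
}

#' Fit the trend suite to every stratum of a strata table
#'
#' @param strata [build_strata()] output (long format).
#' @param alpha significance level passed to [mhw_trend()].
#' @param min_years strata with fewer non-missing years draw a warning
#'   (default 10); strata with fewer than 3 usable years are skipped.
#' @return tidy data frame, one row per stratum: `scope`, `stratum`,
#'   `realm`, `season`, `metric`, `n`, `S`, `var_S`, `z`, `p`, `sen_slope`,
#'   `slope_per_decade`, `intercept`, `change_year`, `pettitt_p`,
#'   `before_slope`, `after_slope`, `slope_ratio`, `direction`. The fitted
#'   `mhw_trend` objects are attached as the `fits` attribute.
#' @export
fit_strata <- function(strata, alpha = 0.05, min_years = 10L) {
  ids <- unique(strata$stratum)
  fits <- list(); rows <- list()
  for (id in ids) {
    sub <- strata[strata$stratum == id, , drop = FALSE]
    sub <- sub[order(sub$year), ]
    n_ok <- sum(!is.na(sub$value))
    if (n_ok < 3L) {
      warning(sprintf("stratum %s has only %d usable years; skipped", id, n_ok))
      next
    }
    if (n_ok < min_years) {
      warning(sprintf("stratum %s has n = %d < %d years", id, n_ok, min_years))
    }
    fit <- mhw_trend(sub$value, sub$year, alpha = alpha, stratum = id)
    fits[[id]] <- fit
    rows[[id]] <- data.frame(
      scope = sub$scope[1], stratum = id, realm = sub$realm[1],
      season = sub$season[1], metric = sub$metric[1],
      n = fit$mk$n, S = fit$mk$S, var_S = fit$mk$var_S, z = fit$mk$z,
      p = fit$mk$p, sen_slope = fit$sen$slope,
      slope_per_decade = fit$sen$slope_per_decade,
      intercept = fit$sen$intercept,
      change_year = if (!is.null(fit$pettitt)) fit$pettitt$change_year else NA,
      pettitt_p = if (!is.null(fit$pettitt)) fit$pettitt$p else NA_real_,
      before_slope = if (!is.null(fit$before)) fit$before$sen$slope else NA_real_,
      after_slope = if (!is.null(fit$after)) fit$after$sen$slope else NA_real_,
      slope_ratio = fit$slope_ratio,
      direction = fit$direction)
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  attr(out, "fits") <- fits
  out
}
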