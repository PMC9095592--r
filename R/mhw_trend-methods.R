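# S3 methods for the fitted trend-suite object.

#' @export
print.mhw_trend <- function(x, ...) {
  cat("Nonparametric trend suite", if (!is.null(x$stratum))
    sprintf("for stratum '%s'", x$stratum), "\n")
  cat(sprintf("  n = %d years (%s-%s)\n", x$mk$n, min(x$years), max(x$years)))
  cat(sprintf("  Mann-Kendall: S = %d, z = %.3f, p = %.4g\n",
              x$mk$S, x$mk$z, x$mk$p))
  cat(sprintf("  Theil-Sen slope: %.4g per year (%.4g per decade)\n",
              x$sen$slope, x$sen$slope_per_decade))
  if (!is.null(x$pettitt)) {
    cat(sprintf("  Pettitt: change year %s, K = %g, p = %.4g\n",
                format(x$pettitt$change_year), x$pettitt$K, x$pettitt$p))
  }
  cat(sprintf("  Direction at alpha = %g: %s\n", x$alpha, x$direction))
  invisible(x)
}

#' Summary of a fitted trend suite
#'
#' Adds the before/after re-fit around the Pettitt change year to the
#' printed output.
#'
#' @param object an `mhw_trend` fit.
#' @param ... unused.
#' @export
summary.mhw_trend <- function(object, ...) {
  print(object)
  seg <- function(s, label) {
    if (is.null(s)) {
      cat(sprintf("  %s change year: unavailable (< 3 years)\n", label))
    } else {
      cat(sprintf("  %s change year: slope %.4g/yr, MK p = %.4g (n = %d)\n",
                  label, s$sen$slope, s$mk$p, s$mk$n))
    }
  }
  seg(object$before, "before")
  seg(object$after, "after ")
  if (!is.na(object$slope_ratio)) {
    cat(sprintf("  after/before slope magnitude ratio: %.3g\n",
                object$slope_ratio))
  }
  invisible(object)
}

#' @export
coef.mhw_trend <- function(object, ...) {
  c(intercept = object$sen$intercept, slope = object$sen$slope)
}

#' Theil-Sen trendline values
#'
#' @param object an `mhw_trend` fit.
#' @param years years at which to evaluate the trendline (default the fitted
#'   years).
#' @param ... unused.
#' @export
predict.mhw_trend <- function(object, years = object$years, ...) {
  object$sen$intercept + object$sen$slope * years
}

#' @export
residuals.mhw_trend <- function(object, ...) {
  object$values - predict(object)
}

#' Plot a fitted trend suite
#'
#' Yearly values with the full-series Theil-Sen trendline, the before/after
#' segment trendlines, and the Pettitt change year.
#'
#' @param x an `mhw_trend` fit.
#' @param ... passed to `plot.default`.
#' @export
plot.mhw_trend <- function(x, ...) {
  plot(x$years, x$values, type = "b", pch = 16, xlab = "year",
       ylab = if (!is.null(x$stratum)) x$stratum else "value", ...)
  abline(x$sen$intercept, x$sen$slope, col = "grey40", lwd = 2)
  seg_line <- function(s, yrs, col) {
    if (is.null(s)) return(invisible())
    lines(range(yrs), s$sen$intercept + s$sen$slope * range(yrs),
          col = col, lwd = 2, lty = 2)
  }
  if (!is.null(x$pettitt)) {
    cy <- x$pettitt$change_year
    abline(v = cy - 0.5, col = "firebrick", lty = 3)
    seg_line(x$before, x$years[x$years < cy], "steelblue")
    seg_line(x$after, x$years[x$years >= cy], "firebrick")
    legend("topleft", bty = "n", lwd = 2, lty = c(1, 2, 2),
           col = c("grey40", "steelblue", "firebrick"),
           legend = c("Theil-Sen (full)", "before change", "after change"))
  }
  invisible(x)
}
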