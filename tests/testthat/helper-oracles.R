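# Brute-force reference implementations: explicit pairwise enumeration and
# day-wise scans, deliberately naive, used as independent oracles for the
# production code.

oracle_mk_S <- function(v) {
  n <- length(v); S <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) S <- S + sign(v[j] - v[i])
  S
}

oracle_sen_slope <- function(v, yrs) {
  slopes <- c()
  n <- length(v)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    slopes <- c(slopes, (v[j] - v[i]) / (yrs[j] - yrs[i]))
  }
  median(slopes)
}

oracle_pettitt_U <- function(v) {
  n <- length(v)
  sapply(1:(n - 1), function(t) {
    u <- 0
    for (i in 1:t) for (j in (t + 1):n) u <- u + sign(v[i] - v[j])
    u
  })
}

# explicit flag/run/merge enumeration for the detector
oracle_detect_runs <- function(flagged, min_duration = 5, max_gap = 2) {
  n <- length(flagged)
  runs <- list(); start <- NA
  for (i in seq_len(n)) {
    if (flagged[i] && is.na(start)) start <- i
    if ((!flagged[i] || i == n) && !is.na(start)) {
      end <- if (flagged[i]) i else i - 1
      if (end - start + 1 >= min_duration) runs[[length(runs) + 1]] <- c(start, end)
      start <- NA
    }
  }
  if (length(runs) <= 1) return(runs)
  merged <- list(runs[[1]])
  for (k in 2:length(runs)) {
    prev <- merged[[length(merged)]]
    gap <- runs[[k]][1] - prev[2] - 1
    if (gap <= max_gap) {
      merged[[length(merged)]] <- c(prev[1], runs[[k]][2])
    } else merged[[length(merged) + 1]] <- runs[[k]]
  }
  merged
}

# explicit pooling + sort-based (type 7) percentile climatology, no smoothing
oracle_climatology_raw <- function(dates, sst, half_width, prob) {
  slots <- doy_slot(dates)
  active <- setdiff(1:366, 60)
  q7 <- function(x, p) {
    x <- sort(x); n <- length(x)
    h <- (n - 1) * p
    lo <- floor(h) + 1
    if (lo >= n) return(x[n])
    x[lo] + (h - floor(h)) * (x[lo + 1] - x[lo])
  }
  res <- lapply(active, function(d) {
    dist <- pmin(abs(slots - d), 366 - abs(slots - d))
    pool <- sst[dist <= half_width]
    c(mean = mean(pool), thr = q7(pool, prob))
  })
  out <- do.call(rbind, res)
  rownames(out) <- active
  out
}

# fixtures -------------------------------------------------------------

# constant climatology object for toy detector tests
make_const_clim <- function(clim_mean = 10, clim_threshold = 11) {
  structure(list(slot = 1:366,
                 clim_mean = rep(clim_mean, 366),
                 clim_threshold = rep(clim_threshold, 366),
                 baseline_start = as.Date("2000-01-01"),
                 baseline_end = as.Date("2001-12-31"),
                 percentile = 90, window_half_width = 5L, smooth_width = 31L,
                 pixel_id = "toy"),
            class = "mhw_climatology")
}

# toy series: baseline value plus named exceedance blocks
make_toy_series <- function(n = 60, base = 10, blocks = list(),
                            start = "2000-01-01", pixel_id = "toy") {
  sst <- rep(base, n)
  for (b in blocks) sst[b$idx] <- b$value
  sst_series(pixel_id, seq(as.Date(start), by = "day", length.out = n), sst)
}

ar1_series <- function(n, phi, sd = 1) {
  as.numeric(stats::filter(rnorm(n, sd = sd), phi, method = "recursive"))
}
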