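# Independent oracle implementations used to cross-check the package.

# Brute-force heatwave scan: explicit day-by-day loop, run collection,
# gap merging and metric computation, written independently of detect_events().
oracle_detect <- function(sst, dates, thr, mu, min_dur = 5, max_gap = 2) {
  n <- length(sst)
  exceed <- !is.na(sst) & sst > thr
  runs <- list()
  i <- 1L
  while (i <= n) {
    if (exceed[i]) {
      j <- i
      while (j < n && exceed[j + 1L]) j <- j + 1L
      if (j - i + 1L >= min_dur) runs[[length(runs) + 1L]] <- c(i, j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(runs)) return(NULL)
  merged <- list(runs[[1]])
  for (k in seq_along(runs)[-1]) {
    last <- merged[[length(merged)]]
    if (runs[[k]][1] - last[2] - 1L <= max_gap) {
      merged[[length(merged)]] <- c(last[1], runs[[k]][2])
    } else {
      merged[[length(merged) + 1L]] <- runs[[k]]
    }
  }
  do.call(rbind, lapply(merged, function(se) {
    idx <- se[1]:se[2]
    a <- sst[idx] - mu[idx]
    peak <- which.max(a)
    m <- length(idx)
    data.frame(
      start_date = dates[se[1]], end_date = dates[se[2]], duration = m,
      onset_rate = if (peak > 1) (a[peak] - a[1]) / (peak - 1) else NA_real_,
      decline_rate = if (peak < m) (a[peak] - a[m]) / (m - peak) else NA_real_,
      mean_intensity = mean(a), max_intensity = max(a),
      cumulative_intensity = sum(a))
  }))
}

# constant climatology covering all 366 days
const_clim <- function(mean_c, p90_c) {
  tibble::tibble(day_of_year = 1:366, clim_mean = mean_c, clim_p90 = p90_c)
}

# a planar 7x7 patch: depth = base + sx * east_m + sy * south_m (m per m)
plane_patch <- function(sx = 0, sy = 0, base = 10, cell = 10) {
  idx <- seq_len(7) - 4
  depths <- base + outer(idx * cell * sy, idx * cell * sx, "+")
  structure(list(depths = depths, cell_m = cell), class = "bw_patch")
}

# deterministic consecutive-day series builder
day_series <- function(values, start = as.Date("2010-01-01")) {
  tibble::tibble(date = start + seq_along(values) - 1, sst = values)
}
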