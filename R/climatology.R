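#' Day-of-year SST climatology with a percentile threshold
#'
#' For every day of the year, pools the SST values within a centred window of
#' `window_halfwidth` days across all baseline years, and computes the
#' climatological mean and the 90th-percentile threshold from the pooled
#' sample. Both series are then smoothed with a circular moving average of
#' `smooth_width` days (the convention of the standard marine-heatwave
#' definition: +/- 5-day pooling, 31-day smoothing). Leap days are folded to
#' day 366, whose statistics come from the pooled sample around Feb 29 and are
#' left unsmoothed.
#'
#' @param series tibble with `date` and `sst` for one site.
#' @param baseline_start,baseline_end climatological baseline (must span at
#'   least one year and be covered by `series`).
#' @param window_halfwidth days pooled on each side of the target day.
#' @param smooth_width moving-average width (days); 0 or 1 disables smoothing.
#' @param probs percentile for the threshold (default 0.9).
#' @return tibble with `day_of_year` (1-366), `clim_mean`, `clim_p90`.
#' @export
build_climatology <- function(series, baseline_start, baseline_end,
                              window_halfwidth = 5, smooth_width = 31,
                              probs = 0.9) {
  stopifnot_scalar_date(baseline_start, "baseline_start")
  stopifnot_scalar_date(baseline_end, "baseline_end")
  if (as.numeric(baseline_end - baseline_start) < 364) {
    abort("baseline span must be at least one year")
  }
  if (min(series$date) > baseline_start || max(series$date) < baseline_end) {
    abort("series does not cover the climatological baseline")
  }
  base <- series[series$date >= baseline_start & series$date <= baseline_end, ]
  doy <- pseudo_doy(base$date)
  sst <- base$sst
  w <- as.integer(window_halfwidth)

  # pooled samples for regular days 1..365, windows wrap circularly
  by_doy <- split(sst, factor(doy, levels = 1:366))
  raw_mean <- numeric(365)
  raw_thr <- numeric(365)
  for (d in 1:365) {
    days <- ((d - w - 1):(d + w - 1)) %% 365 + 1
    pool <- unlist(by_doy[days], use.names = FALSE)
    raw_mean[d] <- mean(pool, na.rm = TRUE)
    raw_thr[d] <- quantile(pool, probs, na.rm = TRUE, names = FALSE, type = 7)
  }
  sm_mean <- circ_ma(raw_mean, smooth_width)
  sm_thr <- circ_ma(raw_thr, smooth_width)

  # day 366: pooled sample centred on the Feb 28/Mar 1 boundary plus Feb 29
  feb29_days <- unique(((60 - w):(59 + w) - 1) %% 365 + 1)
  pool366 <- unlist(by_doy[c(feb29_days, 366)], use.names = FALSE)
  m366 <- mean(pool366, na.rm = TRUE)
  t366 <- quantile(pool366, probs, na.rm = TRUE, names = FALSE, type = 7)

  tibble(day_of_year = 1:366,
         clim_mean = c(sm_mean, m366),
         clim_p90 = c(sm_thr, t366))
}

# circular moving average of width `width` (odd widths centred; <=1 = identity)
circ_ma <- function(x, width) {
  width <- as.integer(width)
  if (width <= 1L) return(x)
  half <- width %/% 2L
  n <- length(x)
  xx <- c(x[(n - half + 1):n], x, x[1:half])
  as.numeric(stats::filter(xx, rep(1 / width, width), sides = 2))[(half + 1):(half + n)]
}
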