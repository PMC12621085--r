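#' Generate daily SST series for each site
#'
#' Daily sea-surface temperature per site as a hemisphere-phased seasonal
#' sinusoid plus a latitudinal mean gradient (warmer toward the Equator),
#' AR(1) noise, and rectangular heatwave anomalies injected from the truth
#' ledger. Southern-hemisphere sites peak around early February (day 45),
#' northern sites around mid August (day 220); seasonal amplitude grows with
#' absolute latitude. The deterministic part depends only on the day of the
#' year, so with `noise_sd = 0` the series equals its own day-of-year
#' climatological mean.
#'
#' @param sites site table from [generate_sites()].
#' @param truth [truth_ledger()]; supplies `ar1_coef`, `noise_sd` and
#'   `injected_events`.
#' @param start_date,end_date span of the series; must cover the
#'   climatological baseline plus the survey era and all injected events.
#' @param seed integer seed.
#' @return tibble with `site_id`, `date`, `sst` (deg C).
#' @export
generate_sst_series <- function(sites, truth, start_date, end_date, seed = 1L) {
  stopifnot_scalar_date(start_date, "start_date")
  stopifnot_scalar_date(end_date, "end_date")
  if (end_date <= start_date) abort("`end_date` must be after `start_date`")
  ev <- truth$injected_events
  if (!is.null(ev)) {
    if (any(ev$start_date < start_date | ev$end_date > end_date)) {
      abort("injected event outside the date span")
    }
    if (!all(ev$site_id %in% sites$site_id)) {
      abort("injected event refers to an unknown site")
    }
  }
  dates <- seq(start_date, end_date, by = "day")
  doy <- pseudo_doy(dates)
  nd <- length(dates)
  set.seed(as.integer(seed))

  out <- purrr::map(seq_len(nrow(sites)), function(i) {
    lat <- sites$lat[i]
    clim <- sst_climatology_curve(lat, doy)
    eps <- rnorm(nd, sd = truth$noise_sd)
    noise <- if (truth$noise_sd > 0) {
      as.numeric(stats::filter(eps, truth$ar1_coef, method = "recursive"))
    } else {
      numeric(nd)
    }
    sst <- clim + noise
    if (!is.null(ev)) {
      evi <- ev[ev$site_id == sites$site_id[i], , drop = FALSE]
      for (k in seq_len(nrow(evi))) {
        hit <- dates >= evi$start_date[k] & dates <= evi$end_date[k]
        sst[hit] <- sst[hit] + evi$anomaly[k]
      }
    }
    tibble(site_id = sites$site_id[i], date = dates, sst = sst)
  })
  dplyr::bind_rows(out)
}

# deterministic seasonal curve: equatorward mean gradient + hemisphere-phased
# sinusoid whose amplitude grows with |lat|
sst_climatology_curve <- function(lat, doy) {
  mean_sst <- 29 - 3.5 * (abs(lat) / 35)^2
  amp <- 0.8 + 2.4 * abs(lat) / 35
  peak <- if (lat >= 0) 220 else 45
  mean_sst + amp * cos(2 * pi * (doy - peak) / 365.25)
}
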