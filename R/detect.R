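#' Detect marine heatwaves in a daily SST series
#'
#' A marine heatwave is at least `min_duration` (default 5) consecutive days
#' with SST strictly above the day-of-year 90th-percentile climatological
#' threshold. Qualifying runs separated by at most `max_gap` below-threshold
#' days are merged into a single event. Event metrics are computed from daily
#' anomalies relative to the climatological mean over all days from event
#' start to end (gap days included): mean, maximum and cumulative intensity,
#' and onset/decline rates between the start/end days and the (first) peak
#' day. Rates are `NA` when the peak coincides with the start or end day.
#'
#' @param series tibble with `date` and `sst` for one site; dates must be
#'   consecutive days.
#' @param clim climatology from [build_climatology()].
#' @param min_duration minimum run length in days.
#' @param max_gap maximum below-threshold gap (days) joined across.
#' @return tibble of events with `event_id`, `start_date`, `end_date`,
#'   `duration`, `onset_rate`, `decline_rate`, `mean_intensity`,
#'   `max_intensity`, `cumulative_intensity`, and a `daily` list-column of
#'   per-day anomalies (used for survey-truncated metrics).
#' @export
detect_events <- function(series, clim, min_duration = 5, max_gap = 2) {
  stopifnot(all(c("date", "sst") %in% names(series)))
  if (nrow(series) == 0) return(empty_events())
  d <- diff(as.numeric(series$date))
  if (length(d) && any(d != 1)) abort("`series` must be consecutive daily values")
  doy <- pseudo_doy(series$date)
  thr <- clim$clim_p90[doy]
  mu <- clim$clim_mean[doy]
  if (anyNA(thr)) abort("climatology does not cover the series dates")
  exceed <- !is.na(series$sst) & series$sst > thr

  r <- rle(exceed)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  qual <- which(r$values & r$lengths >= min_duration)
  if (!length(qual)) return(empty_events())

  # merge qualifying runs separated by gaps of at most max_gap days
  ev_start <- starts[qual]
  ev_end <- ends[qual]
  merged_start <- ev_start[1]
  merged_end <- ev_end[1]
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(ev_start)[-1]) {
    if (ev_start[i] - merged_end - 1L <= max_gap) {
      merged_end <- ev_end[i]
    } else {
      out_s <- c(out_s, merged_start); out_e <- c(out_e, merged_end)
      merged_start <- ev_start[i]; merged_end <- ev_end[i]
    }
  }
  out_s <- c(out_s, merged_start); out_e <- c(out_e, merged_end)

  anom <- series$sst - mu
  evs <- purrr::map(seq_along(out_s), function(k) {
    idx <- out_s[k]:out_e[k]
    a <- anom[idx]
    peak <- which.max(a)  # first day attaining the maximum
    n <- length(idx)
    tibble(
      start_date = series$date[out_s[k]],
      end_date = series$date[out_e[k]],
      duration = n,
      onset_rate = if (peak > 1) (a[peak] - a[1]) / (peak - 1) else NA_real_,
      decline_rate = if (peak < n) (a[peak] - a[n]) / (n - peak) else NA_real_,
      mean_intensity = mean(a),
      max_intensity = max(a),
      cumulative_intensity = sum(a),
      daily = list(tibble(date = series$date[idx], anomaly = a)))
  })
  out <- dplyr::bind_rows(evs)
  out$event_id <- seq_len(nrow(out))
  dplyr::relocate(out, "event_id")
}

empty_events <- function() {
  tibble(event_id = integer(0), start_date = as.Date(character(0)),
         end_date = as.Date(character(0)), duration = integer(0),
         onset_rate = numeric(0), decline_rate = numeric(0),
         mean_intensity = numeric(0), max_intensity = numeric(0),
         cumulative_intensity = numeric(0), daily = list())
}

#' Link one survey date to detected heatwave events
#'
#' A survey is exposed to a heatwave if it falls inside an event or at most
#' `max_lag_days` (default 14) after an event's end. Inside an event, the
#' duration to survey is the literal date difference `survey - start` and the
#' cumulative intensity sums daily anomalies up to and including the survey
#' day; within the lag window after an event, the event's total duration and
#' total cumulative intensity are used. When several events qualify, an event
#' containing the survey date wins, otherwise the most recently ended one.
#'
#' @param events event table from [detect_events()], sorted by `start_date`.
#' @param survey_date a Date.
#' @param max_lag_days exposure window after an event's end.
#' @return one-row tibble: `active`, `event_id`, `duration_to_survey`,
#'   `cumulative_to_survey`.
#' @export
link_survey <- function(events, survey_date, max_lag_days = 14) {
  stopifnot_scalar_date(survey_date, "survey_date")
  inactive <- tibble(active = FALSE, event_id = NA_integer_,
                     duration_to_survey = 0, cumulative_to_survey = 0)
  if (nrow(events) == 0) return(inactive)

  inside <- which(events$start_date <= survey_date & events$end_date >= survey_date)
  if (length(inside)) {
    i <- inside[[1]]
    day <- events$daily[[i]]
    upto <- day$anomaly[day$date <= survey_date]
    return(tibble(active = TRUE, event_id = events$event_id[i],
                  duration_to_survey = as.numeric(survey_date - events$start_date[i]),
                  cumulative_to_survey = sum(upto)))
  }
  lag <- as.numeric(survey_date - events$end_date)
  recent <- which(lag > 0 & lag <= max_lag_days)
  if (length(recent)) {
    i <- recent[which.max(events$end_date[recent])]
    return(tibble(active = TRUE, event_id = events$event_id[i],
                  duration_to_survey = as.numeric(events$duration[i]),
                  cumulative_to_survey = events$cumulative_intensity[i]))
  }
  inactive
}

#' Link many survey dates at once
#'
#' @inheritParams link_survey
#' @param survey_dates vector of Dates.
#' @return tibble with one row per survey date (in input order), columns as
#'   [link_survey()] plus `survey_date`.
#' @export
link_surveys <- function(events, survey_dates, max_lag_days = 14) {
  out <- purrr::map(survey_dates, link_survey, events = events,
                    max_lag_days = max_lag_days)
  dplyr::bind_cols(tibble(survey_date = survey_dates), dplyr::bind_rows(out))
}

#' Average annual frequency of historical heatwaves
#'
#' Counts events whose start date lies between `window_years[2]` (default
#' 15.5) and `window_years[1]` (default 0.5) years before the survey and
#' divides by the window length in years (15). Events within half a year of
#' the survey are excluded so modern heatwaves are not counted as historical;
#' events more than 15.5 years before are excluded so the window stays inside
#' the temperature record. A year is 365.25 days.
#'
#' @param events event table from [detect_events()].
#' @param survey_date a Date.
#' @param window_years `c(near, far)` bounds in years before the survey.
#' @return events per year (`>= 0`).
#' @export
historical_frequency <- function(events, survey_date, window_years = c(0.5, 15.5)) {
  stopifnot_scalar_date(survey_date, "survey_date")
  yr <- 365.25
  lo <- survey_date - window_years[2] * yr
  hi <- survey_date - window_years[1] * yr
  n <- sum(events$start_date >= lo & events$start_date <= hi)
  n / (window_years[2] - window_years[1])
}
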