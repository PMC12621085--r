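test_that("climatology of a constant series is the constant", {
  s <- day_series(rep(25, 800), start = as.Date("2000-01-01"))
  cl <- build_climatology(s, as.Date("2000-01-01"), as.Date("2001-12-31"))
  expect_equal(nrow(cl), 366)
  expect_equal(cl$clim_mean, rep(25, 366), tolerance = 1e-12)
  expect_equal(cl$clim_p90, rep(25, 366), tolerance = 1e-12)
})

test_that("with no pooling or smoothing the climatological mean is the sinusoid", {
  dates <- seq(as.Date("2001-01-01"), as.Date("2003-12-31"), by = "day")
  doy <- as.integer(format(dates, "%j"))
  vals <- 26 + 2 * cos(2 * pi * (doy - 45) / 365.25)
  s <- tibble::tibble(date = dates, sst = vals)
  cl <- build_climatology(s, dates[1], dates[length(dates)],
                          window_halfwidth = 0, smooth_width = 0)
  expect_equal(cl$clim_mean[doy], vals, tolerance = 1e-12)
  expect_equal(cl$clim_p90[doy], vals, tolerance = 1e-12)
})

test_that("pooled-window percentiles match a brute-force oracle", {
  set.seed(42)
  dates <- seq(as.Date("2001-01-01"), as.Date("2003-12-31"), by = "day")
  s <- tibble::tibble(date = dates, sst = rnorm(length(dates), 26, 1.5))
  w <- 2
  cl <- build_climatology(s, dates[1], dates[length(dates)],
                          window_halfwidth = w, smooth_width = 0)
  doy <- bleachwave:::pseudo_doy(dates)
  for (d in c(1, 60, 200, 365)) {
    wanted <- ((d - w - 1):(d + w - 1)) %% 365 + 1
    pool <- s$sst[doy %in% wanted]
    expect_equal(cl$clim_mean[d], mean(pool), tolerance = 1e-12)
    expect_equal(cl$clim_p90[d], quantile(pool, 0.9, names = FALSE),
                 tolerance = 1e-12)
  }
  expect_error(build_climatology(s, dates[1], dates[1] + 100), "at least one year")
  expect_error(build_climatology(s, dates[1] - 10, dates[length(dates)]),
               "cover")
})

test_that("four exceedance days never form an event; five do", {
  cl <- const_clim(25, 25.5)
  base <- rep(25, 60)
  s4 <- base; s4[20:23] <- 27
  expect_equal(nrow(detect_events(day_series(s4), cl)), 0)
  s5 <- base; s5[20:24] <- 27
  ev <- detect_events(day_series(s5), cl)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration, 5)
})

test_that("threshold limits give one whole-series event or none", {
  s <- day_series(25 + sin(1:100))
  expect_equal(nrow(detect_events(s, const_clim(25, Inf))), 0)
  ev <- detect_events(s, const_clim(25, -Inf))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration, 100)
})

test_that("qualifying runs merge across short gaps only", {
  cl <- const_clim(25, 25.5)
  v <- rep(25, 80)
  v[10:15] <- 27; v[18:22] <- 27     # gap of 2 days -> merged
  ev <- detect_events(day_series(v), cl)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration, 13)
  v2 <- rep(25, 80)
  v2[10:15] <- 27; v2[19:24] <- 27   # gap of 3 days -> separate
  ev2 <- detect_events(day_series(v2), cl)
  expect_equal(nrow(ev2), 2)
  # a 3-day exceedance between events does not itself qualify or join
  v3 <- rep(25, 80)
  v3[10:15] <- 27; v3[20:22] <- 27
  expect_equal(nrow(detect_events(day_series(v3), cl)), 1)
})

test_that("event metrics and boundaries match the brute-force oracle on random series", {
  set.seed(7)
  cl <- const_clim(25, 25.4)
  for (k in 1:60) {
    v <- 25 + as.numeric(arima.sim(list(ar = 0.7), 300, sd = 0.5))
    s <- day_series(v)
    ev <- detect_events(s, cl)
    orc <- oracle_detect(v, s$date, rep(25.4, 300), rep(25, 300))
    if (is.null(orc)) {
      expect_equal(nrow(ev), 0)
    } else {
      expect_equal(nrow(ev), nrow(orc))
      expect_equal(ev$start_date, orc$start_date)
      expect_equal(ev$end_date, orc$end_date)
      expect_equal(ev$duration, orc$duration)
      expect_equal(ev$onset_rate, orc$onset_rate, tolerance = 1e-12)
      expect_equal(ev$decline_rate, orc$decline_rate, tolerance = 1e-12)
      expect_equal(ev$mean_intensity, orc$mean_intensity, tolerance = 1e-12)
      expect_equal(ev$max_intensity, orc$max_intensity, tolerance = 1e-12)
      expect_equal(ev$cumulative_intensity, orc$cumulative_intensity,
                   tolerance = 1e-12)
    }
  }
})

test_that("detection is pure: identical inputs give identical events", {
  set.seed(9)
  v <- 25 + rnorm(200, 0, 0.6)
  s <- day_series(v)
  cl <- const_clim(25, 25.3)
  expect_identical(detect_events(s, cl), detect_events(s, cl))
})

test_that("survey linkage follows the stated duration and 14-day rules", {
  cl <- const_clim(25, 25.5)
  v <- rep(25, 200)
  v[100:120] <- 28   # event days 100..120 (1-based index = day number)
  s <- day_series(v, start = as.Date("2015-01-01") - 1 + 1)
  ev <- detect_events(s, cl)
  start <- ev$start_date
  # inside the event: literal date subtraction and truncated accumulation
  l5 <- link_survey(ev, start + 5)
  expect_true(l5$active)
  expect_equal(l5$duration_to_survey, 5)
  expect_equal(l5$cumulative_to_survey, 6 * 3)  # six days of +3 anomalies
  # within 14 days after the end: totals are used
  l14 <- link_survey(ev, ev$end_date + 14)
  expect_true(l14$active)
  expect_equal(l14$duration_to_survey, ev$duration)
  expect_equal(l14$cumulative_to_survey, ev$cumulative_intensity)
  # one day later: inactive
  l15 <- link_survey(ev, ev$end_date + 15)
  expect_false(l15$active)
  expect_equal(l15$cumulative_to_survey, 0)
})

test_that("cumulative intensity to survey is nondecreasing within an event", {
  set.seed(11)
  cl <- const_clim(25, 25.3)
  v <- 25 + as.numeric(arima.sim(list(ar = 0.8), 250, sd = 0.6))
  s <- day_series(v)
  ev <- detect_events(s, cl)
  expect_gt(nrow(ev), 0)
  e1 <- ev[which.max(ev$duration), ]
  days <- seq(e1$start_date, e1$end_date, by = "day")
  cums <- vapply(days, function(d) link_survey(ev, d)$cumulative_to_survey,
                 numeric(1))
  expect_true(all(diff(cums) >= -1e-12))
})

test_that("a survey inside an event is linked to it, not to a recent one", {
  ev <- tibble::tibble(
    event_id = 1:2,
    start_date = as.Date(c("2015-01-01", "2015-01-20")),
    end_date = as.Date(c("2015-01-10", "2015-02-05")),
    duration = c(10L, 17L), onset_rate = 1, decline_rate = 1,
    mean_intensity = 2, max_intensity = 3,
    cumulative_intensity = c(20, 34),
    daily = list(
      tibble::tibble(date = seq(as.Date("2015-01-01"), by = "day", length.out = 10),
                     anomaly = 2),
      tibble::tibble(date = seq(as.Date("2015-01-20"), by = "day", length.out = 17),
                     anomaly = 2)))
  l <- link_survey(ev, as.Date("2015-01-22"))  # inside event 2, 12 d after event 1
  expect_equal(l$event_id, 2L)
  expect_equal(l$duration_to_survey, 2)
})

test_that("historical frequency counts events in the 0.5-15.5 year window", {
  mk <- function(starts) {
    tibble::tibble(start_date = as.Date(starts))
  }
  survey <- as.Date("2018-06-01")
  six <- mk(survey - round(365.25 * c(1, 3, 5, 8, 12, 15)))
  expect_equal(historical_frequency(six, survey), 6 / 15)
  expect_equal(historical_frequency(mk(survey - 0.4 * 365.25), survey), 0)
  expect_equal(historical_frequency(mk(survey - 16 * 365.25), survey), 0)
  # boundary inclusion at exactly 0.5 and 15.5 years
  expect_equal(historical_frequency(mk(survey - 0.5 * 365.25), survey), 1 / 15)
  expect_equal(historical_frequency(mk(survey - 15.5 * 365.25), survey), 1 / 15)
})
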