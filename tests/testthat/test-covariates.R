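test_that("window means follow the stated alignment and missing-day policy", {
  dates <- seq(as.Date("2020-01-01"), as.Date("2020-03-31"), by = "day")
  s <- tibble::tibble(date = dates, value = 25)
  survey <- as.Date("2020-02-15")
  expect_equal(as.numeric(window_mean(s, survey, 30)), 25)

  # the survey day itself only counts when included
  s2 <- s
  s2$value[s2$date == survey] <- 100
  excl <- window_mean(s2, survey, 30)
  incl <- window_mean(s2, survey, 30, include_survey_day = TRUE)
  expect_equal(as.numeric(excl), 25)
  expect_gt(as.numeric(incl), 25)

  # half-missing windows use available days; attributes report the gaps
  s3 <- s
  s3$value[seq(2, nrow(s3), by = 2)] <- NA
  wm <- window_mean(s3, survey, 30)
  expect_equal(as.numeric(wm), 25)
  expect_equal(attr(wm, "n_available") + attr(wm, "n_missing"), 30)

  # brute-force arithmetic oracle
  set.seed(1)
  s4 <- tibble::tibble(date = dates, value = rnorm(length(dates)))
  idx <- s4$date >= survey - 30 & s4$date <= survey - 1
  expect_equal(as.numeric(window_mean(s4, survey, 30)),
               sum(s4$value[idx]) / 30, tolerance = 1e-12)

  # below minimum coverage -> missing
  s5 <- s
  s5$value[s5$date < survey] <- NA
  expect_true(is.na(window_mean(s5, survey, 30)))
})

test_that("current speed is the Euclidean magnitude", {
  expect_equal(current_speed(0, 0), 0)
  expect_equal(current_speed(3, 4), 5)
  expect_equal(current_speed(-1, 1), sqrt(2))
  expect_equal(current_speed(c(3, -3), c(4, -4)), c(5, 5))
})

test_that("wave energy follows the quadratic closed form", {
  expect_equal(wave_energy(0), 0)
  expect_equal(wave_energy(1), 0.125 * 1025 * 9.81, tolerance = 1e-12)
  expect_equal(wave_energy(1), 1256.90625, tolerance = 1e-9)
  hs <- c(0.5, 1.2, 2.4)
  expect_equal(wave_energy(2 * hs), 4 * wave_energy(hs), tolerance = 1e-12)
  expect_error(wave_energy(-0.1), ">= 0")
})

test_that("tidal range doubles the constituent sum and is symmetric", {
  expect_equal(tidal_range(0, 0, 0, 0), 0)
  expect_equal(tidal_range(0.5, 0.25, 0.15, 0.10), 2.0, tolerance = 1e-12)
  expect_equal(tidal_range(0.10, 0.15, 0.25, 0.5), 2.0, tolerance = 1e-12)
  expect_error(tidal_range(-0.1, 0, 0, 0), ">= 0")
})

test_that("sampling effort counts surveys per ecoregion-month-year cell", {
  sv <- tibble::tibble(
    ecoregion_id = c(1, 1, 1, 2, 2, 3),
    year = c(2010, 2010, 2010, 2010, 2011, 2012),
    month = c(5, 5, 5, 5, 5, 6))
  out <- sampling_effort(sv)
  expect_equal(out$sampling_effort, c(3, 3, 3, 1, 1, 1))
  # counts partition the table: summing one count per cell recovers the size
  expect_equal(sum(out$sampling_effort[!duplicated(
    out[c("ecoregion_id", "year", "month")])]), nrow(sv))
})

test_that("standardization gives exact z-scores and the stated interaction", {
  set.seed(2)
  d <- tibble::tibble(temperature = rnorm(200, 28, 1),
                      irradiance = rnorm(200, 40, 5),
                      depth = runif(200, 1, 20))
  out <- standardize_covariates(d)
  for (cl in c("z_temperature", "z_irradiance", "z_depth")) {
    expect_lt(abs(mean(out[[cl]])), 1e-10)
    expect_lt(abs(sd(out[[cl]]) - 1), 1e-10)
  }
  expect_equal(out$z_temperature_irradiance,
               out$z_temperature * out$z_irradiance, tolerance = 1e-12)
  # brute-force formula
  expect_equal(out$z_depth, (d$depth - mean(d$depth)) / sd(d$depth),
               tolerance = 1e-12)
  d$flatline <- 7
  expect_error(standardize_covariates(d, cols = c("depth", "flatline")),
               "flatline")
})

test_that("collinearity screen prunes to pairwise |r| below the threshold", {
  set.seed(3)
  n <- 500
  a <- rnorm(n)
  d <- tibble::tibble(a = a, b = a, c = rnorm(n), e = rnorm(n))
  scr <- collinearity_screen(d, threshold = 0.6)
  expect_length(intersect(c("a", "b"), scr$retained), 1)
  expect_true(all(c("c", "e") %in% scr$retained))
  expect_true(any(scr$report$r == 1))
  # independent noise columns all retained
  noise <- tibble::as_tibble(as.data.frame(matrix(rnorm(n * 6), n)))
  expect_length(collinearity_screen(noise)$dropped, 0)
  # zero threshold leaves a single survivor
  expect_length(collinearity_screen(d, threshold = 0)$retained, 1)
})
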