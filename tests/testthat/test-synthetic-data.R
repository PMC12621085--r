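test_that("generated sites respect the sampling band and are seed-deterministic", {
  s <- generate_sites(100, seed = 1)
  expect_equal(nrow(s), 100)
  expect_false(any(duplicated(s$site_id)))
  expect_true(all(abs(s$lat) <= 35))
  expect_true(all(s$lon >= -180 & s$lon < 180))
  expect_true(all(s$depth > 0 & s$depth <= 20))
  expect_true(all(s$ocean_id %in% 1:3))
  expect_true(all(s$source_id %in% 1:9))
  expect_identical(s, generate_sites(100, seed = 1))
  expect_error(generate_sites(1), "at least|>= 2|must")
})

test_that("site clustering produces both local and basin-scale distances", {
  s <- generate_sites(500, seed = 2)
  dall <- bleachwave:::sphere_dist(latlon_to_unit_sphere(s$lat, s$lon),
                                   metric = "greatcircle") * 6371
  off <- dall[upper.tri(dall)]
  expect_true(any(off < 50))
  expect_true(any(off > 5000))
})

test_that("noise-free SST equals its own day-of-year climatological mean", {
  sites <- generate_sites(2, seed = 3)
  tr0 <- truth_ledger(noise_sd = 0)
  sst <- generate_sst_series(sites, tr0, as.Date("2000-01-01"),
                             as.Date("2005-12-31"), seed = 1)
  s1 <- sst[sst$site_id == sites$site_id[1], ]
  clim_means <- ave(s1$sst, format(s1$date, "%m-%d"), FUN = mean)
  expect_equal(s1$sst, clim_means, tolerance = 1e-12)
})

test_that("seasonal peak follows the hemisphere", {
  sites <- tibble::tibble(site_id = 1:2, lat = c(-20, 20), lon = c(100, 100),
                          depth = 5, ecoregion_id = 1, ocean_id = 1, source_id = 1)
  tr <- truth_ledger(noise_sd = 0)
  sst <- generate_sst_series(sites, tr, as.Date("2010-01-01"),
                             as.Date("2010-12-31"), seed = 1)
  south <- sst[sst$site_id == 1, ]
  north <- sst[sst$site_id == 2, ]
  peak_s <- as.integer(format(south$date[which.max(south$sst)], "%j"))
  peak_n <- as.integer(format(north$date[which.max(north$sst)], "%j"))
  expect_true(peak_s >= 1 && peak_s <= 90)      # Jan-Mar
  expect_true(peak_n >= 182 && peak_n <= 273)   # Jul-Sep
})

test_that("an injected warm anomaly is found by the detector", {
  sites <- generate_sites(2, seed = 4)
  ev <- tibble::tibble(site_id = sites$site_id[1],
                       start_date = as.Date("2016-03-01"),
                       end_date = as.Date("2016-03-10"), anomaly = 3)
  tr <- truth_ledger(injected_events = ev)
  sst <- generate_sst_series(sites, tr, as.Date("1985-01-01"),
                             as.Date("2020-12-31"), seed = 5)
  s1 <- sst[sst$site_id == sites$site_id[1], ]
  clim <- build_climatology(s1, as.Date("1985-01-01"), as.Date("2014-12-31"))
  found <- detect_events(s1, clim)
  overlap <- found$start_date <= ev$end_date & found$end_date >= ev$start_date
  expect_true(any(overlap))
  # events outside the series span are rejected
  expect_error(generate_sst_series(sites, tr, as.Date("2017-01-01"),
                                   as.Date("2020-12-31"), seed = 1),
               "outside")
})

test_that("bathymetry patch kinds have their analytic structure", {
  flat <- generate_bathymetry_patch("flat")
  expect_true(all(flat$depths == flat$depths[1, 1]))
  tilt <- generate_bathymetry_patch("tilted-plane")
  expect_true(all(apply(tilt$depths, 2, function(cl) diff(cl)) == 1))
  bump <- generate_bathymetry_patch("bump")
  ann <- sqrt(outer((1:7 - 4)^2, (1:7 - 4)^2, "+")) * 10 >= 20
  expect_true(all(bump$depths[4, 4] < bump$depths[ann]))
  expect_true(all(generate_bathymetry_patch("rough", seed = 9)$depths > 0))
  expect_identical(generate_bathymetry_patch("rough", seed = 9)$depths,
                   generate_bathymetry_patch("rough", seed = 9)$depths)
})

test_that("ordered-beta branch probabilities integrate to one (independent formula)", {
  for (eta in c(-2, 0, 1.5)) {
    for (k1 in c(-1, 0)) {
      p0 <- 1 - plogis(eta - k1)
      p1 <- plogis(eta - 3)
      mu <- plogis(eta)
      cont <- integrate(function(y) {
        (plogis(eta - k1) - plogis(eta - 3)) * dbeta(y, mu * 6, (1 - mu) * 6)
      }, 0, 1, rel.tol = 1e-12)$value
      expect_equal(p0 + p1 + cont, 1, tolerance = 1e-12)
    }
  }
})

test_that("cutpoint limits drive outcomes to the boundaries or the interior", {
  set.seed(1)
  open <- rordbeta(2000, eta = 0, k1 = -30, k2 = 30, phi = 4)
  expect_true(all(open > 0 & open < 1))
  zeros <- rordbeta(2000, eta = -30, k1 = 0, k2 = 3, phi = 4)
  expect_true(all(zeros == 0))
  ones <- rordbeta(2000, eta = 30, k1 = 0, k2 = 3, phi = 4)
  expect_true(all(ones == 1))
})

test_that("the default truth yields about half zero-bleaching surveys", {
  sites <- generate_sites(150, seed = 6, n_regions = 25)
  sv <- generate_surveys(sites, truth_ledger(), n_per_site = 70, seed = 6)
  expect_gt(nrow(sv), 1e4)
  expect_true(abs(mean(sv$proportion == 0) - 0.5) < 0.10)
  # determinism of the full generator
  sv2 <- generate_surveys(sites, truth_ledger(), n_per_site = 3, seed = 8)
  sv3 <- generate_surveys(sites, truth_ledger(), n_per_site = 3, seed = 8)
  expect_identical(sv2$proportion, sv3$proportion)
  expect_identical(latent_draws(sv2)$u, latent_draws(sv3)$u)
})

test_that("surveys carry covariates below the collinearity threshold", {
  sites <- generate_sites(120, seed = 7, n_regions = 25)
  sv <- generate_surveys(sites, truth_ledger(), n_per_site = 10, seed = 7)
  scr <- collinearity_screen(sv, cols = setdiff(covariate_names(),
                                                "temperature_irradiance"))
  expect_length(scr$dropped, 0)
})

test_that("gamma intensity generator matches its stated moments", {
  sites <- generate_sites(500, seed = 10)
  flat <- generate_gamma_intensities(sites, beta0 = 0.5, betaL = 0, shape = 2,
                                     seed = 1, n_per_site = 20)
  expect_equal(mean(flat$intensity), exp(0.5), tolerance = 0.05)
  expo <- generate_gamma_intensities(sites, beta0 = 0, betaL = 0, shape = 1,
                                     seed = 2, n_per_site = 20)
  expect_equal(sd(expo$intensity) / mean(expo$intensity), 1, tolerance = 0.05)
  grad <- generate_gamma_intensities(sites, beta0 = 0.3, betaL = 0.4, shape = 2,
                                     seed = 3, n_per_site = 20)
  bins <- cut(abs(grad$lat), c(0, 10, 20, 35))
  mns <- tapply(grad$intensity, bins, mean)
  expect_true(all(diff(mns) > 0))
  expect_error(generate_gamma_intensities(sites, 0, 0, shape = -1), "> 0")
})
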