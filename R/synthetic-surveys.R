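#' Draw bleaching outcomes from the full generative model
#'
#' Given a survey schedule and a covariate matrix, draws every latent
#' component from the truth ledger (Matern field over the sites, RW1 year
#' effect over 2002-2020, cyclic RW1 month effect per hemisphere, iid
#' ocean/site/source intercepts, optional observation error), assembles the
#' linear predictor, and samples ordered-beta outcomes. The realized latent
#' values are attached for recovery tests (see [latent_draws()]).
#'
#' @param schedule tibble with `site_id`, `lat`, `lon`, `date` or
#'   `year`+`month`, `ocean_id`, `source_id`.
#' @param z numeric matrix of standardized covariates aligned with `schedule`;
#'   columns must be named.
#' @param truth a [truth_ledger()]; `truth$beta` is matched to `colnames(z)`
#'   by name (columns without a matching name get coefficient 0).
#' @param seed integer seed.
#' @return `schedule` with `eta` and `proportion` columns appended; attribute
#'   `latent` holds the realized effects.
#' @export
simulate_outcomes <- function(schedule, z, truth, seed = 1L) {
  if (truth$k1 >= truth$k2) abort("cutpoints must satisfy k1 < k2")
  s <- schedule
  if (!all(c("year", "month") %in% names(s))) {
    s$year <- date_year(s$date)
    s$month <- date_month(s$date)
  }
  n <- nrow(s)
  set.seed(as.integer(seed))

  sites <- dplyr::distinct(s[, c("site_id", "lat", "lon")], .data$site_id,
                           .keep_all = TRUE)
  sites <- dplyr::arrange(sites, .data$site_id)
  S <- nrow(sites)

  # Matern latent field over the site set
  kap <- sqrt(8) / (truth$spatial_range_km / 6371)
  xyz <- latlon_to_unit_sphere(sites$lat, sites$lon)
  C <- matern_correlation(sphere_dist(xyz), kap, 1)
  diag(C) <- diag(C) + 1e-8
  u <- setNames(drop(crossprod(chol(C), rnorm(S))) * truth$spatial_sd,
                sites$site_id)

  years <- 2002:2020
  year_effect <- setNames(rrw1(length(years), truth$rw_sd_year), years)
  month_effect <- tibble(
    month = rep(1:12, 2),
    hemisphere = rep(c("north", "south"), each = 12),
    effect = c(rrw1(12, truth$rw_sd_month, cyclic = TRUE),
               rrw1(12, truth$rw_sd_month, cyclic = TRUE)))
  centred <- function(k, sd) { x <- rnorm(k, sd = sd); x - mean(x) }
  oceans <- sort(unique(s$ocean_id))
  sources <- sort(unique(s$source_id))
  ocean_effect <- setNames(centred(length(oceans), truth$iid_sds[["ocean"]]), oceans)
  site_effect <- setNames(centred(S, truth$iid_sds[["site"]]), sites$site_id)
  source_effect <- setNames(centred(length(sources), truth$iid_sds[["source"]]),
                            sources)

  beta <- setNames(numeric(ncol(z)), colnames(z))
  hit <- intersect(names(truth$beta), colnames(z))
  beta[hit] <- truth$beta[hit]
  # z columns produced by standardize_covariates() carry a z_ prefix
  hit_z <- intersect(paste0("z_", names(truth$beta)), colnames(z))
  beta[hit_z] <- truth$beta[sub("^z_", "", hit_z)]

  if (!all(s$year %in% years)) abort("survey years must lie in 2002-2020")
  comp <- assemble_linear_predictor(
    s, z, truth$beta0, beta, u = u, year_effect = year_effect,
    month_effect = month_effect, ocean_effect = ocean_effect,
    site_effect = site_effect, source_effect = source_effect)
  eta <- comp$eta
  if (truth$sigma_eps > 0) eta <- eta + rnorm(n, sd = truth$sigma_eps)

  schedule$eta <- eta
  schedule$proportion <- rordbeta(n, eta, truth$k1, truth$k2, truth$phi)
  attr(schedule, "latent") <- list(
    u = u, year = year_effect, month = month_effect, ocean = ocean_effect,
    site = site_effect, source = source_effect, eta = eta,
    components = comp)
  schedule
}

#' Realized latent effects of a simulated survey table
#'
#' @param surveys output of [simulate_outcomes()] or [generate_surveys()].
#' @return list with `u`, `year`, `month`, `ocean`, `site`, `source`, `eta`.
#' @export
latent_draws <- function(surveys) attr(surveys, "latent")

#' Generate a complete synthetic bleaching survey table
#'
#' Builds a survey schedule (dates uniform over 2002-2020), synthesizes the 18
#' raw covariates with mild latitudinal gradients emulating the observed
#' exploratory patterns (warmer and cloudier toward the Equator, more intense
#' historical heatwave exposure toward higher latitude), standardizes them,
#' and draws ordered-beta outcomes through [simulate_outcomes()]. The
#' gradients are qualitative: only their signs matter for the sign-recovery
#' tests, and their magnitudes are kept small enough that all pairwise
#' covariate correlations stay below the 0.6 collinearity screen.
#'
#' @param sites site table from [generate_sites()].
#' @param truth a [truth_ledger()].
#' @param n_per_site surveys per site.
#' @param seed integer seed.
#' @return survey tibble with raw and `z_`-prefixed covariates, `eta`,
#'   `proportion`; latent draws attached (see [latent_draws()]).
#' @export
generate_surveys <- function(sites, truth, n_per_site = 10, seed = 1L) {
  set.seed(as.integer(seed))
  n <- nrow(sites) * n_per_site
  idx <- rep(seq_len(nrow(sites)), each = n_per_site)
  s <- sites[idx, ]
  s$year <- sample(2002:2020, n, replace = TRUE)
  s$month <- sample(12L, n, replace = TRUE)
  s$date <- as.Date(sprintf("%d-%02d-%02d", s$year, s$month,
                            sample(28L, n, replace = TRUE)))
  lf <- abs(s$lat) / 35

  site_col <- function(x) x[idx]  # site-level quantity expanded to surveys
  raw <- tibble(
    temperature = 28.5 - 1.2 * lf^2 + rnorm(n, sd = 1),
    irradiance = 42 - 4 * lf + rnorm(n, sd = 4),
    cumulative_intensity = pmax(rnorm(n, 6 + 3 * lf, 4), 0),
    heatwave_frequency = pmax(rnorm(n, 0.4 + 0.2 * lf, 0.25), 0),
    turbidity = stats::rlnorm(n, log(0.08), 0.5),
    current_velocity = 0.15 + abs(rnorm(n, sd = 0.12)),
    wave_energy = rgamma(n, 2, scale = 600),
    tidal_range = site_col(abs(rnorm(nrow(sites), 1.8, 0.8))),
    cloud_frequency = pmin(pmax(45 + 15 * exp(-(s$lat / 12)^2) +
                                  rnorm(n, sd = 10), 0), 100),
    depth = s$depth,
    rugosity = site_col(abs(rnorm(nrow(sites), 0.35, 0.25))),
    slope = site_col(pmin(abs(rnorm(nrow(sites), 8, 6)), 60)),
    polar_alignment = site_col(runif(nrow(sites), -1, 1)),
    bpi = site_col(rnorm(nrow(sites), sd = 1.5)),
    abs_latitude = abs(s$lat),
    coral_cover = runif(n, 5, 80))
  surveys <- dplyr::bind_cols(
    s[, c("site_id", "lat", "lon", "ecoregion_id", "ocean_id", "source_id",
          "date", "year", "month")], raw)
  surveys <- sampling_effort(surveys)
  surveys <- standardize_covariates(surveys)
  zcols <- paste0("z_", covariate_names())
  z <- as.matrix(surveys[zcols])
  simulate_outcomes(surveys, z, truth, seed = child_seed(seed, 7L))
}

#' Generate heatwave intensities from the gamma-latitude model
#'
#' Intensities drawn from a gamma distribution whose log mean is linear in
#' standardized absolute latitude: `I ~ Gamma(shape, scale = mu/shape)` with
#' `mu = exp(beta0 + betaL * z_lat)`. Optional site, spatial and temporal
#' effects exercise the full hierarchical structure.
#'
#' @param sites site table.
#' @param beta0 intercept (log scale).
#' @param betaL coefficient of standardized absolute latitude.
#' @param shape gamma shape, `> 0`.
#' @param seed integer seed.
#' @param n_per_site events per site.
#' @param spatial_sd,spatial_range_km,site_sd,rw_sd_year,rw_sd_month optional
#'   random-effect scales (0 disables each).
#' @return tibble with `site_id`, `lat`, `lon`, `year`, `month`,
#'   `z_abs_latitude`, `eta`, `intensity`.
#' @export
generate_gamma_intensities <- function(sites, beta0, betaL, shape, seed = 1L,
                                       n_per_site = 1, spatial_sd = 0,
                                       spatial_range_km = 300, site_sd = 0,
                                       rw_sd_year = 0, rw_sd_month = 0) {
  if (!is.numeric(shape) || shape <= 0) abort("`shape` must be > 0")
  set.seed(as.integer(seed))
  n <- nrow(sites) * n_per_site
  idx <- rep(seq_len(nrow(sites)), each = n_per_site)
  out <- sites[idx, c("site_id", "lat", "lon")]
  out$year <- sample(2002:2020, n, replace = TRUE)
  out$month <- sample(12L, n, replace = TRUE)
  al <- abs(out$lat)
  out$z_abs_latitude <- (al - mean(al)) / sd(al)

  eta <- beta0 + betaL * out$z_abs_latitude
  if (spatial_sd > 0) {
    xyz <- latlon_to_unit_sphere(sites$lat, sites$lon)
    kap <- sqrt(8) / (spatial_range_km / 6371)
    C <- matern_correlation(sphere_dist(xyz), kap, 1)
    diag(C) <- diag(C) + 1e-8
    u <- drop(crossprod(chol(C), rnorm(nrow(sites)))) * spatial_sd
    eta <- eta + u[idx]
  }
  if (site_sd > 0) {
    l <- rnorm(nrow(sites), sd = site_sd)
    eta <- eta + (l - mean(l))[idx]
  }
  if (rw_sd_year > 0) {
    ye <- setNames(rrw1(19, rw_sd_year), 2002:2020)
    eta <- eta + ye[as.character(out$year)]
  }
  if (rw_sd_month > 0) {
    me <- rbind(rrw1(12, rw_sd_month, cyclic = TRUE),
                rrw1(12, rw_sd_month, cyclic = TRUE))
    eta <- eta + me[cbind(ifelse(out$lat >= 0, 1L, 2L), out$month)]
  }
  out$eta <- as.numeric(eta)
  out$intensity <- rgamma(n, shape = shape, scale = exp(out$eta) / shape)
  out
}
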