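#' Ground-truth parameter ledger for the synthetic study
#'
#' Collects every generating parameter of the synthetic bleaching study: the
#' ordered-beta regression coefficients, cutpoints and precision, the Matern
#' latent-field scale and range, temporal random-walk scales, iid intercept
#' scales, SST noise structure, and the heatwave anomalies to inject. Defaults
#' reproduce the qualitative sign pattern reported for global bleaching
#' analyses (warming, cumulative heatwave stress, latitude and sampling effort
#' positive; irradiance, currents, turbidity, clouds, wave energy and historical
#' heatwave frequency negative; depth, tides, cover and topography null) with a
#' roughly 50% zero-bleaching rate.
#'
#' @param beta0 intercept of the linear predictor.
#' @param beta named vector of 18 fixed-effect coefficients on standardized
#'   covariates; names must equal [covariate_names()].
#' @param k1,k2 ordered cutpoints, `k1 < k2`.
#' @param phi beta precision, `> 0`.
#' @param spatial_sd,spatial_range_km marginal sd and nominal range (km) of the
#'   Matern latent field.
#' @param rw_sd_year,rw_sd_month scales of the annual RW1 and cyclic monthly
#'   RW1 effects.
#' @param iid_sds named vector with `ocean`, `site`, `source` iid intercept sds.
#' @param sigma_eps sd of per-observation Gaussian measurement error on the
#'   linear-predictor scale (0 disables it; it is near-confounded with the
#'   site intercept for single-visit sites).
#' @param ar1_coef,noise_sd AR(1) coefficient and innovation sd (deg C) of the
#'   daily SST noise.
#' @param injected_events data frame of rectangular SST anomalies with columns
#'   `site_id`, `start_date`, `end_date`, `anomaly` (deg C); each must span at
#'   least 5 days.
#' @param seed integer seed recorded with the truth.
#' @return a `bw_truth` list.
#' @export
truth_ledger <- function(beta0 = 0,
                         beta = default_beta(),
                         k1 = 0, k2 = 3, phi = 8,
                         spatial_sd = 0.75, spatial_range_km = 300,
                         rw_sd_year = 0.3, rw_sd_month = 0.25,
                         iid_sds = c(ocean = 0.25, site = 0.2, source = 0.25),
                         sigma_eps = 0,
                         ar1_coef = 0.8, noise_sd = 0.4,
                         injected_events = NULL,
                         seed = 1L) {
  if (k1 >= k2) abort("cutpoints must satisfy k1 < k2")
  if (phi <= 0) abort("`phi` must be > 0")
  sds <- c(spatial_sd, rw_sd_year, rw_sd_month, iid_sds)
  if (any(sds <= 0)) abort("all scale parameters must be > 0")
  if (sigma_eps < 0) abort("`sigma_eps` must be >= 0")
  if (!identical(sort(names(beta)), sort(covariate_names()))) {
    abort("`beta` must be named by covariate_names()")
  }
  beta <- beta[covariate_names()]
  if (!all(c("ocean", "site", "source") %in% names(iid_sds))) {
    abort("`iid_sds` needs ocean, site, source entries")
  }
  if (!is.null(injected_events)) {
    injected_events <- as_tibble(injected_events)
    span <- as.numeric(injected_events$end_date - injected_events$start_date) + 1
    if (any(span < 5)) abort("every injected event must span >= 5 days")
  }
  structure(
    list(beta0 = beta0, beta = beta, k1 = k1, k2 = k2, phi = phi,
         spatial_sd = spatial_sd, spatial_range_km = spatial_range_km,
         rw_sd_year = rw_sd_year, rw_sd_month = rw_sd_month,
         iid_sds = iid_sds, sigma_eps = sigma_eps,
         ar1_coef = ar1_coef, noise_sd = noise_sd,
         injected_events = injected_events, seed = as.integer(seed)),
    class = "bw_truth")
}

#' Names of the 18 fixed-effect covariates
#'
#' The covariate set of the bleaching model: 30-day temperature, 30-day
#' irradiance, their interaction, survey-truncated cumulative heatwave
#' intensity, historical heatwave frequency, 60-day turbidity, 30-day current
#' velocity, 60-day wave energy, tidal range, monthly cloud frequency, survey
#' depth, rugosity, slope, polar alignment, bathymetric-position index,
#' absolute latitude, hard-coral cover, and sampling effort.
#'
#' @return character vector of length 18.
#' @export
covariate_names <- function() {
  c("temperature", "irradiance", "temperature_irradiance",
    "cumulative_intensity", "heatwave_frequency", "turbidity",
    "current_velocity", "wave_energy", "tidal_range", "cloud_frequency",
    "depth", "rugosity", "slope", "polar_alignment", "bpi",
    "abs_latitude", "coral_cover", "sampling_effort")
}

default_beta <- function() {
  setNames(
    c(0.5, -0.4, 0.3,
      0.45, -0.4, -0.3,
      -0.25, -0.2, 0, -0.3,
      0, 0, 0, 0, 0,
      0.4, 0, 0.2),
    covariate_names())
}

#' Generate clustered reef sites within the tropical sampling band
#'
#' Sites are scattered around a configurable number of region centres so that
#' both short (< 50 km) and basin-scale (> 5000 km) pairwise distances occur,
#' exercising spatial correlation. All sites satisfy |lat| <= 35 degrees and
#' depth <= 20 m.
#'
#' @param n number of sites, `>= 2`.
#' @param seed integer seed.
#' @param n_regions number of cluster centres (also used as ecoregion ids).
#' @param cluster_sd_deg within-region scatter, degrees.
#' @return tibble with `site_id`, `lat`, `lon`, `depth`, `ecoregion_id`,
#'   `ocean_id`, `source_id`.
#' @export
generate_sites <- function(n, seed = 1L, n_regions = 8, cluster_sd_deg = 1.5) {
  if (!is.numeric(n) || n < 2) abort("`n` must be >= 2")
  n <- as.integer(n)
  set.seed(as.integer(seed))
  centres <- tibble(
    ecoregion_id = seq_len(n_regions),
    clat = runif(n_regions, -30, 30),
    clon = runif(n_regions, -180, 180))
  reg <- sample(n_regions, n, replace = TRUE)
  lat <- pmin(pmax(centres$clat[reg] + rnorm(n, sd = cluster_sd_deg), -35), 35)
  lon <- centres$clon[reg] + rnorm(n, sd = cluster_sd_deg)
  lon <- ((lon + 180) %% 360) - 180
  tibble(
    site_id = seq_len(n),
    lat = lat, lon = lon,
    depth = runif(n, 0.5, 20),
    ecoregion_id = reg,
    ocean_id = ((((lon + 180) %/% 120) %% 3) + 1L),
    source_id = sample(9L, n, replace = TRUE))
}

#' Generate a 7x7 analytic bathymetry patch
#'
#' A 70 m x 70 m patch of positive-down depths at 10 m cell spacing, centred
#' on the focal cell (4, 4). Rows run north to south, columns west to east.
#' `kind` selects an analytic surface used to validate the terrain metrics.
#'
#' @param kind one of `"flat"`, `"tilted-plane"`, `"bump"`, `"depression"`,
#'   `"rough"`.
#' @param seed integer seed (only `"rough"` is stochastic).
#' @param base_depth depth of the reference surface, m.
#' @param cell_m cell spacing, m.
#' @return a `bw_patch`: list with `depths` (7x7 matrix, m, positive down) and
#'   `cell_m`.
#' @export
generate_bathymetry_patch <- function(kind = c("flat", "tilted-plane", "bump",
                                               "depression", "rough"),
                                      seed = 1L, base_depth = 10, cell_m = 10) {
  kind <- match.arg(kind)
  set.seed(as.integer(seed))
  idx <- seq_len(7L) - 4L  # offsets from the focal cell in cell units
  r2 <- outer(idx, idx, function(i, j) i^2 + j^2)
  depths <- switch(
    kind,
    "flat" = matrix(base_depth, 7, 7),
    # depth increases linearly with row index (southward)
    "tilted-plane" = matrix(base_depth, 7, 7) + outer(idx, rep(0, 7), "+") * 1.0,
    "bump" = base_depth - 4 * exp(-r2 / 6),
    "depression" = base_depth + 4 * exp(-r2 / 6),
    "rough" = pmax(matrix(base_depth + rnorm(49, sd = 0.8), 7, 7), 0.5))
  structure(list(depths = depths, cell_m = cell_m), class = "bw_patch")
}
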