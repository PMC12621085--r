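#' Fit the ordered-beta spatio-temporal model of bleaching severity
#'
#' Bayesian hierarchical ordered-beta regression of a zero/one-inflated
#' proportion on standardized covariates, with a Matern latent field over the
#' survey sites on the unit sphere, an RW1 year effect, a cyclic RW1
#' month-by-hemisphere effect, and iid ocean/site/source intercepts:
#' \deqn{\eta_i = \beta_0 + \sum_j \beta_j z_{ij} + u_s + \nu_y + \nu_{mh} +
#'       o_k + l_s + d_n}
#' Inference is empirical-Bayes Laplace: the latent-field mode is found by
#' sparse Newton iteration and the Laplace-approximate marginal posterior is
#' maximized over the hyperparameters; reported posteriors are the Gaussian
#' marginals conditional on that mode.
#'
#' @param data tibble with one row per survey: the response column
#'   (proportion bleached in \[0, 1\]), `site_id`, `lat`, `lon`, `year` and
#'   `month` (or a `date` column), `ocean_id` and `source_id` (when iid
#'   effects are enabled), and the covariate columns.
#' @param covariates character vector of covariate column names; defaults to
#'   the `z_`-prefixed standardized set present in `data`.
#' @param response name of the response column.
#' @param control a [bw_control()] list.
#' @return a `bw_fit` object; see [tidy()], [glance()], [autoplot()],
#'   [project_latent()], [nominal_range()], [summarize_signs()].
#' @export
fit_ordered_beta <- function(data, covariates = NULL, response = "proportion",
                             control = bw_control()) {
  data <- prepare_fit_data(data, response, need_groups = control$use_iid)
  if (nrow(data) < 50) abort("need at least 50 surveys")
  if (dplyr::n_distinct(data$site_id) < 10) abort("need at least 10 sites")
  if (is.null(covariates)) {
    covariates <- intersect(paste0("z_", covariate_names()), names(data))
  }
  if (!length(covariates)) abort("no covariate columns found")
  y <- data[[response]]
  if (any(y < 0 | y > 1)) abort("response must lie in [0, 1]")
  z <- as.matrix(data[covariates])
  if (anyNA(z)) abort("covariates contain missing values")
  fit_hier_model(data, z, y, model = "ordered_beta", control = control)
}

#' Fit the gamma model of heatwave intensity against absolute latitude
#'
#' Gamma regression (log link) of mean heatwave intensity on standardized
#' absolute latitude, with the same latent structure as the bleaching model
#' except for the ocean and data-source intercepts:
#' \eqn{\eta_i = \beta_0 + \beta_L z_{iL} + u_s + \nu_y + \nu_{mh} + l_s}.
#' The intensity response should be the event's mean intensity over its full
#' duration, restricted to surveys linked to an active or recently active
#' heatwave.
#'
#' @param data tibble with the response column (positive intensities, deg C),
#'   `site_id`, `lat`, `lon`, and `year`/`month` (or `date`).
#' @param response name of the response column.
#' @param control a [bw_control()] list.
#' @return a `bw_fit` object (`model = "gamma"`) whose latitude scaling is
#'   stored for [marginal_intensity_curve()].
#' @export
fit_gamma_latitude <- function(data, response = "intensity",
                               control = bw_control()) {
  data <- prepare_fit_data(data, response, need_groups = FALSE)
  if (nrow(data) < 50) abort("need at least 50 events")
  if (dplyr::n_distinct(data$site_id) < 10) abort("need at least 10 sites")
  y <- data[[response]]
  if (any(y <= 0)) abort("intensities must be > 0")
  al <- abs(data$lat)
  mu <- mean(al); s <- sd(al)
  if (s == 0) abort("absolute latitude has zero variance")
  z <- matrix((al - mu) / s, ncol = 1,
              dimnames = list(NULL, "z_abs_latitude"))
  fit <- fit_hier_model(data, z, y, model = "gamma", control = control)
  fit$lat_scaling <- c(mean = mu, sd = s)
  fit
}

prepare_fit_data <- function(data, response, need_groups) {
  req <- c(response, "site_id", "lat", "lon")
  miss <- setdiff(req, names(data))
  if (length(miss)) abort(paste("missing columns:", paste(miss, collapse = ", ")))
  if (!all(c("year", "month") %in% names(data))) {
    if (!"date" %in% names(data)) abort("need `year`+`month` or `date` columns")
    data$year <- date_year(data$date)
    data$month <- date_month(data$date)
  }
  if (need_groups && !all(c("ocean_id", "source_id") %in% names(data))) {
    abort("iid effects need `ocean_id` and `source_id` columns")
  }
  data
}

#' Assemble the linear predictor from explicit effect components
#'
#' Computes \eqn{\eta_i} as the sum of intercept, fixed effects, spatial,
#' temporal and iid components, indexed exactly as in the hierarchical model,
#' and returns the decomposition for diagnostics. Used by the synthetic
#' generator and testable against brute-force summation.
#'
#' @param data tibble with `site_id`, `year`, `month`, `lat` (for the
#'   hemisphere), and optionally `ocean_id`, `source_id`.
#' @param z numeric matrix of covariates (rows aligned with `data`).
#' @param beta0 intercept.
#' @param beta coefficient vector, length `ncol(z)`.
#' @param u named spatial effects (names = site ids), or NULL.
#' @param year_effect named year effects (names = years), or NULL.
#' @param month_effect tibble with `month`, `hemisphere`, `effect`, or NULL.
#' @param ocean_effect,site_effect,source_effect named iid effects, or NULL.
#' @return tibble with `eta` and one column per component.
#' @export
assemble_linear_predictor <- function(data, z, beta0, beta, u = NULL,
                                      year_effect = NULL, month_effect = NULL,
                                      ocean_effect = NULL, site_effect = NULL,
                                      source_effect = NULL) {
  n <- nrow(data)
  if (!is.null(dim(z)) && nrow(z) != n) abort("`z` rows must match `data`")
  if (length(beta) != ncol(z)) abort("`beta` length must equal ncol(z)")
  pick <- function(effect, keys, what) {
    if (is.null(effect)) return(numeric(n))
    val <- effect[as.character(keys)]
    if (anyNA(val)) abort(paste0("unmatched ", what, " index"))
    as.numeric(val)
  }
  comp <- tibble(
    fixed = as.numeric(z %*% beta),
    spatial = pick(u, data$site_id, "site"),
    year = pick(year_effect, data$year, "year"),
    month = if (is.null(month_effect)) numeric(n) else {
      key <- paste(data$month, hemisphere_of(data$lat))
      tab <- setNames(month_effect$effect,
                      paste(month_effect$month, month_effect$hemisphere))
      val <- tab[key]
      if (anyNA(val)) abort("unmatched month/hemisphere index")
      as.numeric(val)
    },
    ocean = if (is.null(ocean_effect)) numeric(n) else
      pick(ocean_effect, data$ocean_id, "ocean"),
    site = pick(site_effect, data$site_id, "site"),
    source = if (is.null(source_effect)) numeric(n) else
      pick(source_effect, data$source_id, "source"))
  comp$eta <- beta0 + rowSums(comp)
  dplyr::relocate(comp, "eta")
}

#' Project the latent spatial field onto arbitrary locations
#'
#' Conditional Gaussian (kriging) prediction of the latent field at new
#' lat/lon points from the fitted site-level posterior, on the linear-predictor
#' (logit or log) scale. The predictive variance combines the conditional
#' Matern variance with the propagated posterior uncertainty of the site
#' values; far from all sites the mean reverts to 0 and the sd to the
#' marginal field sd.
#'
#' @param fit a `bw_fit` with a spatial field.
#' @param grid tibble with `lat` and `lon` columns.
#' @return `grid` with `mean` and `sd` columns appended.
#' @export
project_latent <- function(fit, grid) {
  if (!inherits(fit, "bw_fit") || is.null(fit$field)) {
    abort("`fit` must be a bw_fit with a spatial field")
  }
  sig <- exp(fit$theta[["log_sigma_u"]])
  kap <- exp(fit$theta[["log_kappa"]])
  nu <- fit$spatial$nu
  xyz_s <- fit$spatial$xyz
  xyz_g <- latlon_to_unit_sphere(grid$lat, grid$lon)
  Css <- matern_correlation(sphere_dist(xyz_s, metric = fit$spatial$metric),
                            kap, nu)
  diag(Css) <- diag(Css) + 1e-8
  Cgs <- matern_correlation(sphere_dist(xyz_g, xyz_s, metric = fit$spatial$metric),
                            kap, nu)
  B <- Cgs %*% chol2inv(chol(Css))
  iu <- fit$blocks$u
  m_u <- fit$x[iu]
  S_u <- fit$Sigma[iu, iu, drop = FALSE]
  mean_g <- as.numeric(B %*% m_u)
  cond_var <- sig^2 * pmax(1 - rowSums(B * Cgs), 0)
  post_var <- rowSums((B %*% S_u) * B)
  grid$mean <- mean_g
  grid$sd <- sqrt(cond_var + post_var)
  grid
}

#' Marginal fitted heatwave-intensity curve over latitude
#'
#' The fitted mean intensity based only on the intercept and the
#' absolute-latitude fixed effect: `exp(b0 + bL * z(|lat|))` summarized over
#' Gaussian posterior draws of `(b0, bL)`, with a central credibility band.
#' `z` uses the standardization constants of the fit.
#'
#' @param fit a `bw_fit` from [fit_gamma_latitude()].
#' @param lat_grid latitudes (degrees) at which to evaluate.
#' @param level credibility level of the band.
#' @param n_draws posterior draws used for the summaries.
#' @param seed seed for the draws.
#' @return tibble with `lat`, `mean`, `lower`, `upper`.
#' @export
marginal_intensity_curve <- function(fit, lat_grid = seq(-35, 35, by = 1),
                                     level = 0.95, n_draws = 4000, seed = 1L) {
  if (!inherits(fit, "bw_fit") || fit$model != "gamma") {
    abort("`fit` must come from fit_gamma_latitude()")
  }
  set.seed(as.integer(seed))
  fx <- fit$blocks$fixed[1:2]
  m <- fit$x[fx]
  V <- fit$Sigma[fx, fx] + diag(1e-12, 2)  # tolerate degenerate posteriors
  L <- chol(V)
  draws <- matrix(rnorm(2 * n_draws), n_draws, 2) %*% L +
    matrix(m, n_draws, 2, byrow = TRUE)
  zl <- (abs(lat_grid) - fit$lat_scaling[["mean"]]) / fit$lat_scaling[["sd"]]
  curves <- exp(outer(draws[, 1], rep(1, length(zl))) +
                  outer(draws[, 2], zl))
  a <- (1 - level) / 2
  tibble(lat = lat_grid,
         mean = colMeans(curves),
         lower = apply(curves, 2, quantile, a),
         upper = apply(curves, 2, quantile, 1 - a))
}

#' Classify fixed-effect relationships by their 90% credibility intervals
#'
#' A coefficient whose 90% interval is entirely positive (negative) marks a
#' positive (negative) relationship; intervals containing zero mark none. The
#' temperature-irradiance interaction is additionally labelled synergistic /
#' additive / antagonistic by the same rule.
#'
#' @param x a `bw_fit` or a posterior summary tibble with `term`, `q05`, `q95`.
#' @return tibble with `term`, `q05`, `q95`, `relationship`, `label`.
#' @export
summarize_signs <- function(x) {
  s <- if (inherits(x, "bw_fit")) x$summary else x
  if (!all(c("term", "q05", "q95") %in% names(s))) {
    abort("need `term`, `q05`, `q95` columns")
  }
  rel <- dplyr::case_when(s$q05 > 0 ~ "positive",
                          s$q95 < 0 ~ "negative",
                          TRUE ~ "none")
  inter <- grepl("temperature_irradiance", s$term)
  label <- ifelse(inter,
                  dplyr::case_when(rel == "positive" ~ "synergistic",
                                   rel == "negative" ~ "antagonistic",
                                   TRUE ~ "additive"),
                  rel)
  tibble(term = s$term, q05 = s$q05, q95 = s$q95,
         relationship = rel, label = label)
}
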