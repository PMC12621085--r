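#' Control settings for the hierarchical model fits
#'
#' Tuning knobs of the Laplace engine and the model structure. Defaults give
#' the full model: Matern (`nu = 1`) latent field on chordal unit-sphere
#' distance, RW1 year effect, cyclic RW1 month-by-hemisphere effect, iid
#' ocean/site/source intercepts, and no observation-level error (it is
#' near-confounded with the site intercept for single-visit sites; switch on
#' with `use_obs_error = TRUE`).
#'
#' @param use_spatial,use_temporal,use_iid,use_obs_error enable the latent
#'   field, the RW1/cyclic-RW1 temporal effects, the iid intercepts, and the
#'   observation-level Gaussian error.
#' @param nu Matern smoothness (1 mirrors the standard choice on a 2-D
#'   manifold).
#' @param distance `"chordal"` (always positive definite, numerically equal to
#'   geodesic at reef scales) or `"greatcircle"`.
#' @param beta_prior_sd Gaussian prior sd on intercept and coefficients.
#' @param sd_prior_scale half-Normal prior scale for random-effect sds.
#' @param phi_prior_shape,phi_prior_rate Gamma prior on the beta precision
#'   (also used for the gamma shape).
#' @param kappa_prior_meanlog,kappa_prior_sdlog log-Normal prior on the
#'   inverse range (default centred on a ~500 km nominal range).
#' @param constraint_precision soft sum-to-zero constraint precision.
#' @param outer_maxit,outer_reltol Nelder-Mead budget for the hyperparameter
#'   search.
#' @param verbose print progress?
#' @return a list of class `bw_control`.
#' @export
bw_control <- function(use_spatial = TRUE, use_temporal = TRUE, use_iid = TRUE,
                       use_obs_error = FALSE, nu = 1,
                       distance = c("chordal", "greatcircle"),
                       beta_prior_sd = 5, sd_prior_scale = 2,
                       phi_prior_shape = 2, phi_prior_rate = 0.5,
                       kappa_prior_meanlog = log(sqrt(8) / (500 / 6371)),
                       kappa_prior_sdlog = 1.5,
                       constraint_precision = 1e6,
                       outer_maxit = 500, outer_reltol = 1e-8,
                       verbose = FALSE) {
  structure(list(
    use_spatial = use_spatial, use_temporal = use_temporal, use_iid = use_iid,
    use_obs_error = use_obs_error, nu = nu, distance = match.arg(distance),
    beta_prior_sd = beta_prior_sd, sd_prior_scale = sd_prior_scale,
    phi_prior_shape = phi_prior_shape, phi_prior_rate = phi_prior_rate,
    kappa_prior_meanlog = kappa_prior_meanlog,
    kappa_prior_sdlog = kappa_prior_sdlog,
    constraint_precision = constraint_precision,
    outer_maxit = outer_maxit, outer_reltol = outer_reltol,
    verbose = verbose), class = "bw_control")
}

# Shared builder: assembles the latent layout, design matrix, prior precision
# and hyperparameter vector, runs the Laplace engine, and packages summaries.
fit_hier_model <- function(df, z, y, model = c("ordered_beta", "gamma"),
                           control = bw_control()) {
  model <- match.arg(model)
  n <- nrow(df)
  p <- ncol(z)
  use_group_iid <- control$use_iid && model == "ordered_beta"

  sites <- dplyr::distinct(df[, c("site_id", "lat", "lon")], .data$site_id,
                           .keep_all = TRUE)
  sites <- dplyr::arrange(sites, .data$site_id)
  S <- nrow(sites)
  site_idx <- match(df$site_id, sites$site_id)
  years <- seq(min(df$year), max(df$year))
  Y <- length(years)
  year_idx <- match(df$year, years)
  north <- df$lat >= 0

  if (use_group_iid) {
    oceans <- sort(unique(df$ocean_id))
    sources <- sort(unique(df$source_id))
    ocean_idx <- match(df$ocean_id, oceans)
    source_idx <- match(df$source_id, sources)
  }

  # latent layout -------------------------------------------------------
  blocks <- list(fixed = seq_len(p + 1L))
  off <- p + 1L
  add_block <- function(name, size) {
    blocks[[name]] <<- off + seq_len(size)
    off <<- off + size
  }
  if (control$use_spatial) add_block("u", S)
  if (control$use_temporal) {
    if (Y >= 2) add_block("year", Y)
    add_block("month_n", 12L)
    add_block("month_s", 12L)
  }
  if (use_group_iid) add_block("ocean", length(oceans))
  if (control$use_iid) add_block("site", S)
  if (use_group_iid) add_block("source", length(sources))
  if (control$use_obs_error) add_block("obs", n)
  n_lat <- off

  # sparse design matrix -------------------------------------------------
  ii <- rep(seq_len(n), p + 1L)
  jj <- rep(seq_len(p + 1L), each = n)
  xx <- c(rep(1, n), as.numeric(z))
  add_ind <- function(cols) {
    ii <<- c(ii, seq_len(n)); jj <<- c(jj, cols); xx <<- c(xx, rep(1, n))
  }
  if (control$use_spatial) add_ind(blocks$u[site_idx])
  if (control$use_temporal) {
    if (Y >= 2) add_ind(blocks$year[year_idx])
    mcol <- ifelse(north, blocks$month_n[df$month], blocks$month_s[df$month])
    add_ind(mcol)
  }
  if (use_group_iid) add_ind(blocks$ocean[ocean_idx])
  if (control$use_iid) add_ind(blocks$site[site_idx])
  if (use_group_iid) add_ind(blocks$source[source_idx])
  if (control$use_obs_error) add_ind(blocks$obs)
  A <- sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n_lat))

  # prior precision ------------------------------------------------------
  lam <- control$constraint_precision
  xyz <- latlon_to_unit_sphere(sites$lat, sites$lon)
  D <- if (control$use_spatial) sphere_dist(xyz, metric = control$distance) else NULL
  R_year <- if (control$use_temporal && Y >= 2) rw1_precision(Y) else NULL
  R_cyc <- if (control$use_temporal) rw1_precision(12L, cyclic = TRUE) else NULL
  ones <- function(k) Matrix::Matrix(lam, k, k, sparse = TRUE)

  make_Q <- function(theta) {
    qs <- list(Diagonal(p + 1L, 1 / control$beta_prior_sd^2))
    if (control$use_spatial) {
      sig_u <- exp(theta[["log_sigma_u"]])
      kap <- exp(theta[["log_kappa"]])
      C <- matern_correlation(D, kap, control$nu)
      diag(C) <- diag(C) + 1e-8
      Qu <- chol2inv(chol(C)) / sig_u^2
      qs <- c(qs, list(Matrix::Matrix(Qu, sparse = TRUE)))
    }
    if (control$use_temporal) {
      tau_y <- exp(-2 * theta[["log_sigma_y"]])
      tau_m <- exp(-2 * theta[["log_sigma_m"]])
      if (Y >= 2) qs <- c(qs, list(tau_y * R_year + ones(Y)))
      qs <- c(qs, list(tau_m * R_cyc + ones(12L), tau_m * R_cyc + ones(12L)))
    }
    if (use_group_iid) {
      qs <- c(qs, list(Diagonal(length(oceans), exp(-2 * theta[["log_sigma_o"]])) +
                         ones(length(oceans))))
    }
    if (control$use_iid) {
      qs <- c(qs, list(Diagonal(S, exp(-2 * theta[["log_sigma_l"]])) + ones(S)))
    }
    if (use_group_iid) {
      qs <- c(qs, list(Diagonal(length(sources), exp(-2 * theta[["log_sigma_d"]])) +
                         ones(length(sources))))
    }
    if (control$use_obs_error) {
      qs <- c(qs, list(Diagonal(n, exp(-2 * theta[["log_sigma_e"]]))))
    }
    forceSymmetric(bdiag(qs))
  }

  # hyperparameters ------------------------------------------------------
  theta0 <- numeric(0)
  if (model == "ordered_beta") {
    p0 <- min(max(mean(y == 0), 0.01), 0.99)
    p1 <- min(max(mean(y == 1), 0.002), 0.5)
    k1_0 <- qlogis(p0)
    gap_0 <- log(max(qlogis(1 - p1) - k1_0, 0.3))
    theta0 <- c(theta0, k1 = k1_0, gap = gap_0, log_phi = log(5))
  } else {
    theta0 <- c(theta0, log_k = log(2))
  }
  if (control$use_spatial) {
    theta0 <- c(theta0, log_sigma_u = log(0.4),
                log_kappa = log(sqrt(8) / (300 / 6371)))
  }
  if (control$use_temporal) {
    theta0 <- c(theta0, log_sigma_y = log(0.3), log_sigma_m = log(0.3))
  }
  if (use_group_iid) theta0 <- c(theta0, log_sigma_o = log(0.3))
  if (control$use_iid) theta0 <- c(theta0, log_sigma_l = log(0.3))
  if (use_group_iid) theta0 <- c(theta0, log_sigma_d = log(0.3))
  if (control$use_obs_error) theta0 <- c(theta0, log_sigma_e = log(0.2))

  logprior_theta <- function(theta) {
    lp <- 0
    for (nm in names(theta)) {
      if (startsWith(nm, "log_sigma")) {
        s <- exp(theta[[nm]])
        lp <- lp + dnorm(s, 0, control$sd_prior_scale, log = TRUE) + theta[[nm]]
      }
    }
    if ("log_kappa" %in% names(theta)) {
      lp <- lp + dnorm(theta[["log_kappa"]], control$kappa_prior_meanlog,
                       control$kappa_prior_sdlog, log = TRUE)
    }
    if (model == "ordered_beta") {
      lp <- lp + dnorm(theta[["k1"]], 0, 5, log = TRUE) +
        dnorm(theta[["gap"]], 0, 5, log = TRUE)
      phi <- exp(theta[["log_phi"]])
      lp <- lp + dgamma(phi, control$phi_prior_shape,
                        rate = control$phi_prior_rate, log = TRUE) +
        theta[["log_phi"]]
    } else {
      kk <- exp(theta[["log_k"]])
      lp <- lp + dgamma(kk, control$phi_prior_shape,
                        rate = control$phi_prior_rate, log = TRUE) +
        theta[["log_k"]]
    }
    lp
  }

  make_loglik <- if (model == "ordered_beta") {
    function(theta) {
      k1 <- theta[["k1"]]
      k2 <- k1 + exp(theta[["gap"]])
      phi <- exp(theta[["log_phi"]])
      function(eta) dordbeta(y, eta, k1, k2, phi, log = TRUE)
    }
  } else {
    function(theta) {
      kk <- exp(theta[["log_k"]])
      function(eta) dgamma(y, shape = kk, rate = kk * exp(-eta), log = TRUE)
    }
  }

  res <- lgm_laplace(y, make_loglik, A, make_Q, theta0, logprior_theta,
                     outer_maxit = control$outer_maxit,
                     outer_reltol = control$outer_reltol,
                     verbose = control$verbose)

  # summaries -----------------------------------------------------------
  fx <- blocks$fixed
  terms <- c("(Intercept)", colnames(z))
  summary <- gaussian_summary(terms, res$x[fx], sqrt(diag(res$Sigma)[fx]))

  hyper <- hyper_table(res$theta, model, control)

  field <- NULL
  if (control$use_spatial) {
    iu <- blocks$u
    field <- dplyr::mutate(sites, u_mean = res$x[iu],
                           u_sd = sqrt(diag(res$Sigma)[iu]))
  }
  temporal <- NULL
  if (control$use_temporal && Y >= 2) {
    temporal <- list(
      year = tibble(year = years, effect = res$x[blocks$year],
                    sd = sqrt(diag(res$Sigma)[blocks$year])),
      month = tibble(month = rep(1:12, 2),
                     hemisphere = rep(c("north", "south"), each = 12),
                     effect = c(res$x[blocks$month_n], res$x[blocks$month_s]),
                     sd = sqrt(diag(res$Sigma)[c(blocks$month_n, blocks$month_s)])))
  }

  structure(list(
    model = model, summary = summary, hyper = hyper,
    theta = res$theta, x = res$x, Sigma = res$Sigma, blocks = blocks,
    sites = sites, field = field, temporal = temporal,
    spatial = if (control$use_spatial) {
      list(xyz = xyz, nu = control$nu, metric = control$distance)
    },
    n = n, n_sites = S, years = years,
    marginal_ll = res$marginal_ll,
    diagnostics = list(outer_convergence = res$convergence,
                       outer_evals = res$outer_evals,
                       inner_converged = res$inner_converged),
    control = control), class = "bw_fit")
}

hyper_table <- function(theta, model, control) {
  rows <- list()
  if (model == "ordered_beta") {
    k1 <- theta[["k1"]]; k2 <- k1 + exp(theta[["gap"]])
    rows$k1 <- k1; rows$k2 <- k2; rows$phi <- exp(theta[["log_phi"]])
  } else {
    rows$shape_k <- exp(theta[["log_k"]])
  }
  if ("log_sigma_u" %in% names(theta)) {
    rows$spatial_sd <- exp(theta[["log_sigma_u"]])
    rows$spatial_range_km <- nominal_range(exp(theta[["log_kappa"]]),
                                           nu = control$nu)
  }
  map <- c(log_sigma_y = "rw_sd_year", log_sigma_m = "rw_sd_month",
           log_sigma_o = "iid_sd_ocean", log_sigma_l = "iid_sd_site",
           log_sigma_d = "iid_sd_source", log_sigma_e = "obs_error_sd")
  for (nm in names(map)) {
    if (nm %in% names(theta)) rows[[map[[nm]]]] <- exp(theta[[nm]])
  }
  tibble(parameter = names(rows), estimate = unlist(rows, use.names = FALSE))
}
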