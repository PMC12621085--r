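test_that("linear-predictor assembly matches brute-force summation", {
  d <- tibble::tibble(site_id = c(1, 2, 2, 3), year = c(2005, 2010, 2010, 2019),
                      month = c(1, 6, 12, 7), lat = c(10, -5, -5, 20),
                      ocean_id = c(1, 2, 2, 3), source_id = c(1, 1, 2, 3))
  z <- matrix(0, 4, 2, dimnames = list(NULL, c("a", "b")))
  base <- assemble_linear_predictor(d, z, beta0 = 1.5, beta = c(0, 0))
  expect_equal(base$eta, rep(1.5, 4))
  z[, 1] <- 1
  one <- assemble_linear_predictor(d, z, beta0 = 1.5, beta = c(0.7, 0))
  expect_equal(one$eta, rep(2.2, 4))

  set.seed(6)
  z <- matrix(rnorm(8), 4, 2, dimnames = list(NULL, c("a", "b")))
  beta <- c(0.4, -0.6)
  u <- c(`1` = 0.2, `2` = -0.1, `3` = 0.5)
  ye <- setNames(rnorm(19), 2002:2020)
  me <- tibble::tibble(month = rep(1:12, 2),
                       hemisphere = rep(c("north", "south"), each = 12),
                       effect = rnorm(24))
  oe <- c(`1` = 0.1, `2` = -0.2, `3` = 0.05)
  se <- c(`1` = -0.3, `2` = 0.3, `3` = 0)
  de <- c(`1` = 0.02, `2` = -0.02, `3` = 0.1)
  out <- assemble_linear_predictor(d, z, 0.3, beta, u, ye, me, oe, se, de)
  for (i in 1:4) {
    hemi <- if (d$lat[i] >= 0) "north" else "south"
    expected <- 0.3 + sum(z[i, ] * beta) + u[[as.character(d$site_id[i])]] +
      ye[[as.character(d$year[i])]] +
      me$effect[me$month == d$month[i] & me$hemisphere == hemi] +
      oe[[as.character(d$ocean_id[i])]] + se[[as.character(d$site_id[i])]] +
      de[[as.character(d$source_id[i])]]
    expect_equal(out$eta[i], expected, tolerance = 1e-12)
  }
  expect_error(assemble_linear_predictor(d, z, 0, beta, u = c(`9` = 1)),
               "unmatched")
})

test_that("with all random-effect blocks disabled the fit matches independent ML", {
  set.seed(33)
  n <- 800
  z <- matrix(rnorm(3 * n), n, 3, dimnames = list(NULL, c("x1", "x2", "x3")))
  beta_true <- c(0.6, -0.4, 0)
  eta <- 0.2 + drop(z %*% beta_true)
  d <- tibble::tibble(
    proportion = rordbeta(n, eta, k1 = -0.3, k2 = 2.5, phi = 6),
    site_id = rep(1:20, length.out = n), lat = rep(seq(-30, 30, length.out = 20),
                                                   length.out = n),
    lon = 10, year = 2010, month = 6,
    x1 = z[, 1], x2 = z[, 2], x3 = z[, 3])
  fit <- fit_ordered_beta(d, covariates = c("x1", "x2", "x3"),
                          control = bw_control(use_spatial = FALSE,
                                               use_temporal = FALSE,
                                               use_iid = FALSE,
                                               outer_maxit = 800))

  # independent maximum likelihood: direct optimization of the mixture
  # density written from its definition
  nll <- function(par) {
    b0 <- par[1]; b <- par[2:4]; k1 <- par[5]; k2 <- k1 + exp(par[6])
    phi <- exp(par[7])
    e <- b0 + drop(z %*% b)
    mu <- plogis(e)
    y <- d$proportion
    ll <- numeric(n)
    ll[y == 0] <- log(1 - plogis(e - k1))[y == 0]
    ll[y == 1] <- log(plogis(e - k2))[y == 1]
    mid <- y > 0 & y < 1
    ll[mid] <- log(plogis(e - k1)[mid] - plogis(e - k2)[mid]) +
      dbeta(y[mid], (mu * phi)[mid], ((1 - mu) * phi)[mid], log = TRUE)
    -sum(ll)
  }
  ml <- optim(c(0, 0, 0, 0, qlogis(mean(d$proportion == 0)), 0, log(5)), nll,
              method = "BFGS", control = list(maxit = 500))
  est <- fit$summary$mean
  sds <- fit$summary$sd
  expect_lt(max(abs(est - ml$par[1:4]) / (2 * sds)), 1)
  k1_hat <- fit$hyper$estimate[fit$hyper$parameter == "k1"]
  expect_equal(k1_hat, ml$par[5], tolerance = 0.1)
})

test_that("latent-field projection satisfies the kriging identities", {
  fit <- small_ordbeta_fit()
  # a grid point coincident with a site reproduces its posterior mean
  g1 <- project_latent(fit, fit$sites[3, c("lat", "lon")])
  expect_equal(g1$mean, fit$field$u_mean[3], tolerance = 1e-6)
  # far from every site: prior reversion to mean 0 and the marginal sd
  sig <- exp(fit$theta[["log_sigma_u"]])
  cand <- tidyr::expand_grid(lat = seq(-80, 80, by = 10),
                             lon = seq(-175, 175, by = 10))
  dmin <- apply(bleachwave:::sphere_dist(
    latlon_to_unit_sphere(cand$lat, cand$lon), fit$spatial$xyz), 1, min) * 6371
  far_pt <- cand[which.max(dmin), ]
  expect_gt(max(dmin), 5 * nominal_range(fit))
  far <- project_latent(fit, far_pt)
  expect_lt(abs(far$mean), 1e-3)
  expect_equal(far$sd, sig, tolerance = 0.02)
})

test_that("two-site kriging matches the closed form at the midpoint", {
  sig <- 0.8; kap <- 60
  xyz <- latlon_to_unit_sphere(c(0, 0), c(0, 2))
  fit2 <- structure(list(
    model = "ordered_beta",
    theta = c(log_sigma_u = log(sig), log_kappa = log(kap)),
    spatial = list(xyz = xyz, nu = 1, metric = "chordal"),
    blocks = list(u = 1:2), x = c(0.5, 0.5),
    Sigma = diag(c(1e-6, 1e-6)),
    field = tibble::tibble(site_id = 1:2, lat = 0, lon = c(0, 2),
                           u_mean = 0.5, u_sd = 1e-3),
    control = bw_control()), class = "bw_fit")
  mid <- project_latent(fit2, tibble::tibble(lat = 0, lon = 1))
  # closed form with explicit 2x2 algebra
  dmid <- sqrt(sum((latlon_to_unit_sphere(0, 1) - xyz[1, ])^2))
  d12 <- sqrt(sum((xyz[1, ] - xyz[2, ])^2))
  c0 <- matern_correlation(dmid, kap, 1)
  c12 <- matern_correlation(d12, kap, 1)
  w <- c0 / (1 + 1e-8 + c12)  # equal weights from the 2x2 inverse
  expect_equal(mid$mean, 2 * w * 0.5, tolerance = 1e-6)
  expect_true(mid$mean > 0 && mid$mean <= 0.5 + 1e-9)
})

test_that("a truth without spatial structure yields a near-zero fitted field sd", {
  # the site iid intercept is also kept small: a short-range Matern field is
  # indistinguishable from an iid site effect, so only their combination is
  # testable; 60 sites are needed before small variance components are pinned
  # (see the methods vignette)
  sites <- generate_sites(60, seed = 41, n_regions = 20)
  tr <- truth_ledger(spatial_sd = 1e-3,
                     iid_sds = c(ocean = 0.25, site = 0.05, source = 0.25))
  sv <- generate_surveys(sites, tr, n_per_site = 10, seed = 41)
  fit <- fit_ordered_beta(sv, control = bw_control(outer_maxit = 300))
  # an order of magnitude below the 0.75 field sd the same engine recovers
  # from spatially structured truths
  expect_lt(exp(fit$theta[["log_sigma_u"]]), 0.2)
})

test_that("sign classification follows the 90% interval rule", {
  s <- tibble::tibble(term = c("z_depth", "z_turbidity", "z_temperature_irradiance"),
                      q05 = c(0.1, -0.2, 0.05), q95 = c(0.5, 0.3, 0.4))
  out <- summarize_signs(s)
  expect_equal(out$relationship, c("positive", "none", "positive"))
  expect_equal(out$label, c("positive", "none", "synergistic"))
  s2 <- tibble::tibble(term = c("a", "z_temperature_irradiance"),
                       q05 = c(-0.5, -0.4), q95 = c(-0.1, -0.05))
  expect_equal(summarize_signs(s2)$label, c("negative", "antagonistic"))
})

test_that("fitted objects expose tidy, glance and autoplot interfaces", {
  fit <- small_ordbeta_fit()
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("term", "mean", "sd", "q05", "q50", "q95",
                    "ci90_excludes_zero") %in% names(td)))
  expect_true(all(diff(as.numeric(td[td$term == "z_temperature",
                                     c("q05", "q10", "q25", "q50", "q75",
                                       "q90", "q95")])) > 0))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(gl$nobs == 300 && gl$n_sites == 30)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_output(print(fit), "bw_fit")
})

test_that("the small study recovers strong coefficient signs", {
  fit <- small_ordbeta_fit()
  td <- tidy(fit)
  tr <- small_truth()
  est <- setNames(td$mean[-1], sub("^z_", "", td$term[-1]))
  expect_gt(est[["temperature"]], 0.2)
  expect_lt(est[["irradiance"]], -0.2)
  err <- est[names(tr$beta)] - tr$beta
  expect_lt(max(abs(err)), 0.45)  # coarse bound at n = 300
})
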