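#' Convert latitude/longitude to unit-sphere Cartesian coordinates
#'
#' The Earth is modelled as a unit sphere; distances computed on it are scaled
#' by the volumetric mean radius (6371 km) for reporting.
#'
#' @param lat,lon degrees; vectors of equal length (or length 1, recycled).
#' @return numeric matrix with columns `x`, `y`, `z`, one unit-norm row per point.
#' @export
latlon_to_unit_sphere <- function(lat, lon) {
  n <- max(length(lat), length(lon))
  lat <- rep_len(lat, n) * pi / 180
  lon <- rep_len(lon, n) * pi / 180
  cbind(x = cos(lat) * cos(lon), y = cos(lat) * sin(lon), z = sin(lat))
}

#' Great-circle distances between points on Earth
#'
#' Angles are computed with the numerically stable atan2 form and scaled by
#' `radius_km`.
#'
#' @param lat1,lon1,lat2,lon2 degrees.
#' @param radius_km sphere radius used for reporting; default Earth's
#'   volumetric mean radius.
#' @return distances in km.
#' @export
great_circle_km <- function(lat1, lon1, lat2, lon2, radius_km = 6371) {
  p <- latlon_to_unit_sphere(lat1, lon1)
  q <- latlon_to_unit_sphere(lat2, lon2)
  n <- max(nrow(p), nrow(q))
  p <- p[rep_len(seq_len(nrow(p)), n), , drop = FALSE]
  q <- q[rep_len(seq_len(nrow(q)), n), , drop = FALSE]
  dotpq <- rowSums(p * q)
  crs <- cbind(p[, 2] * q[, 3] - p[, 3] * q[, 2],
               p[, 3] * q[, 1] - p[, 1] * q[, 3],
               p[, 1] * q[, 2] - p[, 2] * q[, 1])
  ang <- atan2(sqrt(rowSums(crs^2)), dotpq)
  unname(ang * radius_km)
}

# pairwise angular (great-circle, radians) or chordal distances on the unit
# sphere between rows of xyz matrices
sphere_dist <- function(xyz1, xyz2 = xyz1, metric = c("chordal", "greatcircle")) {
  metric <- match.arg(metric)
  dotm <- tcrossprod(xyz1, xyz2)
  dotm <- pmin(pmax(dotm, -1), 1)
  if (metric == "greatcircle") acos(dotm) else sqrt(pmax(2 - 2 * dotm, 0))
}

#' Matern correlation function
#'
#' Correlation \eqn{2^{1-\nu}/\Gamma(\nu)\,(\kappa d)^\nu K_\nu(\kappa d)};
#' equals 1 at `d = 0` and decays monotonically. `nu = 1/2` reduces to
#' `exp(-kappa * d)`; `nu = 1` is the standard smoothness for a latent field on
#' a two-dimensional manifold and is the package default.
#'
#' @param d distances `>= 0` (same units as `1/kappa`).
#' @param kappa inverse-range parameter, `> 0`.
#' @param nu smoothness, `> 0`.
#' @return correlations in \[0, 1\].
#' @export
matern_correlation <- function(d, kappa, nu = 1) {
  if (!is.finite(kappa) || kappa <= 0) abort("`kappa` must be > 0")
  if (any(d < 0, na.rm = TRUE)) abort("`d` must be >= 0")
  x <- kappa * d
  out <- numeric(length(x))
  z <- x == 0
  out[z] <- 1
  xn <- x[!z]
  out[!z] <- 2^(1 - nu) / gamma(nu) * xn^nu * besselK(xn, nu)
  dim(out) <- dim(d)
  out
}

#' Nominal range of a Matern field
#'
#' The distance at which the Matern correlation has decayed to roughly 0.1,
#' using the convention `range = sqrt(8 * nu) / kappa`. With `kappa` expressed
#' per radian on the unit sphere, the result is scaled by `radius_km`.
#'
#' @param kappa inverse range (radians^-1 on the unit sphere), or a fitted
#'   model object from [fit_ordered_beta()]/[fit_gamma_latitude()].
#' @param nu smoothness.
#' @param radius_km reporting radius; use 1 to stay in radians.
#' @return range in km (or radians when `radius_km = 1`).
#' @examples
#' nominal_range(sqrt(8) / (100 / 6371))  # ~ 100 km
#' @export
nominal_range <- function(kappa, nu = 1, radius_km = 6371) {
  if (inherits(kappa, "bw_fit")) {
    fit <- kappa
    if (!("log_kappa" %in% names(fit$theta))) abort("fit has no spatial field")
    nu <- fit$control$nu %||% 1
    kappa <- exp(fit$theta[["log_kappa"]])
  }
  if (!is.numeric(kappa) || any(kappa <= 0)) abort("`kappa` must be > 0")
  sqrt(8 * nu) / kappa * radius_km
}

#' Structure matrix of a first-order random walk
#'
#' Returns the (intrinsic) RW1 precision structure `D'D` where `D` takes first
#' differences; the cyclic variant wraps around. Both have rank `n - 1`; a
#' sum-to-zero constraint makes the effect identifiable.
#'
#' @param n number of nodes, `>= 2`.
#' @param cyclic wrap the walk (e.g. calendar months)?
#' @return sparse symmetric `n x n` matrix of class `dsCMatrix`.
#' @export
rw1_precision <- function(n, cyclic = FALSE) {
  if (!is.numeric(n) || n < 2) abort("`n` must be >= 2")
  n <- as.integer(n)
  if (cyclic) {
    i <- seq_len(n)
    j <- c(i, i %% n + 1L)
    D <- sparseMatrix(i = rep(i, 2L), j = j, x = rep(c(1, -1), each = n),
                      dims = c(n, n))
  } else {
    i <- seq_len(n - 1L)
    D <- sparseMatrix(i = rep(i, 2L), j = c(i, i + 1L),
                      x = rep(c(1, -1), each = n - 1L), dims = c(n - 1L, n))
  }
  forceSymmetric(crossprod(D))
}

#' Draw from an intrinsic RW1 prior under a sum-to-zero constraint
#'
#' Samples in the eigenbasis of the structure matrix, giving each non-null
#' eigendirection variance `sd^2 / lambda`, which is the proper distribution of
#' the constrained walk.
#'
#' @param n nodes.
#' @param sd marginal scale of the increments (`1/sqrt(precision)`).
#' @param cyclic wrap?
#' @return numeric vector summing to zero.
#' @export
rrw1 <- function(n, sd, cyclic = FALSE) {
  R <- as.matrix(rw1_precision(n, cyclic))
  e <- eigen(R, symmetric = TRUE)
  keep <- e$values > 1e-9
  z <- rnorm(sum(keep), sd = sd / sqrt(e$values[keep]))
  x <- drop(e$vectors[, keep, drop = FALSE] %*% z)
  x - mean(x)
}
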