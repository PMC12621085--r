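#' Ordered-beta density for zero/one-inflated proportions
#'
#' Density of the ordered-beta distribution: a mixture of point masses at 0 and
#' 1 with a beta density on (0, 1), all driven by one linear predictor `eta`
#' through the logit link and two ordered cutpoints. With
#' \eqn{a = \eta - k_1} and \eqn{b = \eta - k_2},
#' \deqn{P(y = 0) = 1 - \mathrm{logit}^{-1}(a), \quad
#'       P(y = 1) = \mathrm{logit}^{-1}(b),}
#' and for \eqn{0 < y < 1} the density is
#' \eqn{[\mathrm{logit}^{-1}(a) - \mathrm{logit}^{-1}(b)]\,
#'  \mathrm{Beta}(y;\, \mu\phi, (1-\mu)\phi)} with
#' \eqn{\mu = \mathrm{logit}^{-1}(\eta)}. The cutpoint `k1` is the value of the
#' linear predictor below which observing exactly zero becomes more probable
#' than observing an intermediate proportion; `k2` plays the same role for
#' exactly one.
#'
#' @param y proportions in \[0, 1\] (0 and 1 allowed).
#' @param eta linear predictor (recycled against `y`).
#' @param k1,k2 cutpoints, `k1 < k2`.
#' @param phi beta precision, `> 0`.
#' @param log return the log density?
#' @return numeric vector of (log) densities/masses.
#' @examples
#' dordbeta(0, eta = 0, k1 = 0, k2 = 3, phi = 2)   # = 0.5
#' dordbeta(0.5, eta = 0, k1 = -2, k2 = 2, phi = 2)
#' @export
dordbeta <- function(y, eta, k1, k2, phi, log = FALSE) {
  check_cutpoints(k1, k2, phi)
  if (any(y < 0 | y > 1, na.rm = TRUE)) {
    abort("`y` must lie in [0, 1]")
  }
  n <- max(length(y), length(eta))
  y <- rep_len(y, n)
  eta <- rep_len(eta, n)
  a <- eta - k1
  b <- eta - k2
  out <- numeric(n)

  i0 <- y == 0
  i1 <- y == 1
  im <- !i0 & !i1
  # log P(y = 0) = log(1 - invlogit(a))
  out[i0] <- plogis(a[i0], lower.tail = FALSE, log.p = TRUE)
  # log P(y = 1) = log invlogit(b)
  out[i1] <- plogis(b[i1], log.p = TRUE)
  if (any(im)) {
    am <- a[im]; bm <- b[im]
    # log(invlogit(a) - invlogit(b)) = a + log1p(-exp(b - a)) - log1pexp(a) - log1pexp(b)
    log_mid <- am + log1p(-exp(bm - am)) - log1pexp(am) - log1pexp(bm)
    mu <- plogis(eta[im])
    out[im] <- log_mid + dbeta(y[im], mu * phi, (1 - mu) * phi, log = TRUE)
  }
  if (log) out else exp(out)
}

#' Draw ordered-beta outcomes
#'
#' @param n number of draws; `eta` is recycled to length `n`.
#' @inheritParams dordbeta
#' @return numeric vector in \[0, 1\].
#' @export
rordbeta <- function(n, eta, k1, k2, phi) {
  check_cutpoints(k1, k2, phi)
  eta <- rep_len(eta, n)
  p0 <- plogis(eta - k1, lower.tail = FALSE)
  p1 <- plogis(eta - k2)
  u <- runif(n)
  mu <- plogis(eta)
  y <- rbeta(n, mu * phi, (1 - mu) * phi)
  y[u < p0] <- 0
  y[u >= p0 & u < p0 + p1] <- 1
  y
}

#' Total probability mass of the ordered-beta distribution
#'
#' Sums the two point masses and the adaptive-quadrature integral of the
#' continuous component; equals 1 for any valid parameter set, which makes it
#' a direct check of the mixture's normalization.
#'
#' @inheritParams dordbeta
#' @return scalar probability.
#' @export
ordbeta_total_mass <- function(eta, k1, k2, phi) {
  check_cutpoints(k1, k2, phi)
  stopifnot(length(eta) == 1L)
  p0 <- plogis(eta - k1, lower.tail = FALSE)
  p1 <- plogis(eta - k2)
  # integrate the continuous component on the logit scale: with y = invlogit(t)
  # the integrand (density times jacobian) is
  #   delta * exp(-a*log(1+e^-t) - b*log(1+e^t)) / B(a, b),
  # which is finite for every t even when a shape parameter is far below 1
  # and the y-scale density has an endpoint singularity holding most of its
  # mass below double precision
  a <- plogis(eta) * phi
  b <- (1 - plogis(eta)) * phi
  am <- eta - k1
  bm <- eta - k2
  log_delta <- am + log1p(-exp(bm - am)) - log1pexp(am) - log1pexp(bm)
  h <- function(t) exp(log_delta - a * log1pexp(-t) - b * log1pexp(t) -
                         lbeta(a, b))
  cont <- integrate(h, -Inf, Inf, rel.tol = 1e-10)$value
  p0 + p1 + cont
}

check_cutpoints <- function(k1, k2, phi) {
  if (!is.finite(k1) || !is.finite(k2) || k1 >= k2) {
    abort("cutpoints must satisfy k1 < k2")
  }
  if (!is.finite(phi) || phi <= 0) abort("`phi` must be > 0")
  invisible(TRUE)
}
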