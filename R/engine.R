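# Empirical-Bayes Laplace engine for latent Gaussian models.
#
# Model: y_i ~ likelihood(eta_i, theta_lik), eta = A x, x ~ N(0, Q(theta)^-1).
# For fixed hyperparameters theta the latent mode is found by Newton iteration
# with sparse algebra; the Laplace approximation to the marginal likelihood
#   log p(y | theta) ~ loglik(x*) - x*'Qx*/2 + log|Q|/2 - log|H|/2
# (H = Q + A'WA the negative Hessian at the mode) is maximized over theta by
# Nelder-Mead. Posterior summaries are the Gaussian Laplace marginals
# conditional on the hyperparameter mode.

ldet_sym <- function(M) {
  as.numeric(determinant(M, logarithm = TRUE)$modulus)
}

# first/second derivatives of the summed log-likelihood wrt each eta_i,
# by central differences (every likelihood here is smooth in eta)
ll_derivs <- function(loglik, eta, h = 1e-4) {
  l0 <- loglik(eta)
  lp <- loglik(eta + h)
  lm <- loglik(eta - h)
  list(l0 = l0, g1 = (lp - lm) / (2 * h), g2 = (lp - 2 * l0 + lm) / h^2)
}

# Newton ascent to the conditional mode of x | y, theta
inner_mode <- function(loglik, A, Q, x0, maxit = 60, tol = 1e-6) {
  x <- x0
  At <- Matrix::t(A)
  obj <- function(x, l0) sum(l0) - 0.5 * sum(x * as.numeric(Q %*% x))
  eta <- as.numeric(A %*% x)
  d <- ll_derivs(loglik, eta)
  f <- obj(x, d$l0)
  conv <- FALSE
  for (it in seq_len(maxit)) {
    w <- pmax(-d$g2, 1e-8)
    grad <- as.numeric(At %*% d$g1) - as.numeric(Q %*% x)
    if (max(abs(grad)) < tol) { conv <- TRUE; break }
    H <- forceSymmetric(Q + crossprod(A * sqrt(w)))
    ch <- Cholesky(H, LDL = FALSE)
    delta <- as.numeric(solve(ch, grad))
    step <- 1
    repeat {
      x_new <- x + step * delta
      eta_new <- as.numeric(A %*% x_new)
      d_new <- ll_derivs(loglik, eta_new)
      f_new <- obj(x_new, d_new$l0)
      if (is.finite(f_new) && f_new >= f - 1e-12) break
      step <- step / 2
      if (step < 1e-8) break
    }
    if (!is.finite(f_new) || f_new < f - 1e-10) break  # no usable ascent
    x <- x_new; d <- d_new
    moved <- f_new - f
    f <- f_new
    if (moved < 1e-10 * (abs(f) + 1)) { conv <- TRUE; break }
  }
  w <- pmax(-d$g2, 1e-8)
  H <- forceSymmetric(Q + crossprod(A * sqrt(w)))
  list(x = x, f_lik = sum(d$l0), H = H, converged = conv, iterations = it)
}

#' @noRd
lgm_laplace <- function(y, make_loglik, A, make_Q, theta0, logprior_theta,
                        outer_maxit = 500, outer_reltol = 1e-8,
                        verbose = FALSE) {
  n_lat <- ncol(A)
  env <- new.env()
  env$x_warm <- numeric(n_lat)
  env$evals <- 0L

  neg_marginal <- function(theta) {
    names(theta) <- names(theta0)
    Q <- make_Q(theta)
    ll <- make_loglik(theta)
    fit <- inner_mode(ll, A, Q, env$x_warm)
    env$x_warm <- fit$x
    env$evals <- env$evals + 1L
    lml <- fit$f_lik - 0.5 * sum(fit$x * as.numeric(Q %*% fit$x)) +
      0.5 * ldet_sym(Q) - 0.5 * ldet_sym(fit$H) + logprior_theta(theta)
    if (!is.finite(lml)) lml <- -1e10
    if (verbose && env$evals %% 50 == 0) {
      message(sprintf("eval %d: log-marginal %.3f", env$evals, lml))
    }
    -lml
  }

  opt <- optim(theta0, neg_marginal, method = "Nelder-Mead",
               control = list(maxit = outer_maxit, reltol = outer_reltol))
  theta_hat <- setNames(opt$par, names(theta0))

  Q <- make_Q(theta_hat)
  ll <- make_loglik(theta_hat)
  fit <- inner_mode(ll, A, Q, env$x_warm, maxit = 100, tol = 1e-7)
  Sigma <- as.matrix(solve(fit$H))

  list(theta = theta_hat, x = fit$x, Sigma = Sigma,
       marginal_ll = -opt$value,
       convergence = opt$convergence, outer_evals = env$evals,
       inner_converged = fit$converged)
}

# Gaussian posterior summary rows for a set of latent indices
gaussian_summary <- function(term, mean, sd) {
  qs <- c(0.05, 0.10, 0.25, 0.50, 0.75, 0.90, 0.95)
  out <- tibble(term = term, mean = mean, sd = sd)
  for (q in qs) {
    out[[sprintf("q%02d", round(100 * q))]] <- qnorm(q, mean, sd)
  }
  out$ci90_excludes_zero <- out$q05 > 0 | out$q95 < 0
  out
}
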