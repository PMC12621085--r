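#' Gamma log density for heatwave intensities
#'
#' Log density of the gamma distribution parameterized by its log-linear mean:
#' shape `k` and scale `exp(eta)/k`, so that the mean is `exp(eta)` for any
#' shape. This is the likelihood of the heatwave-intensity model.
#'
#' @param I intensities, `> 0` (deg C).
#' @param eta linear predictor (log-link scale).
#' @param k gamma shape, `> 0`.
#' @return log densities.
#' @examples
#' gamma_logdensity(1, eta = 0, k = 1)  # unit exponential: -1
#' @export
gamma_logdensity <- function(I, eta, k) {
  if (any(I <= 0)) abort("`I` must be > 0")
  if (!is.numeric(k) || k <= 0) abort("`k` must be > 0")
  dgamma(I, shape = k, scale = exp(eta) / k, log = TRUE)
}
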