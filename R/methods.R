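#' @export
print.bw_fit <- function(x, ...) {
  cat(sprintf("<bw_fit: %s model, %d observations, %d sites>\n",
              x$model, x$n, x$n_sites))
  cat(sprintf("  Laplace log-marginal: %.2f (outer evals: %d)\n",
              x$marginal_ll, x$diagnostics$outer_evals))
  if (!is.null(x$field)) {
    cat(sprintf("  spatial field: sd %.3f, nominal range %.0f km\n",
                exp(x$theta[["log_sigma_u"]]), nominal_range(x)))
  }
  print(x$summary, n = nrow(x$summary))
  invisible(x)
}

#' Tidy the fixed-effect posterior of a fitted model
#'
#' @param x a `bw_fit`.
#' @param ... unused.
#' @return tibble with one row per fixed effect: posterior `mean`, `sd`,
#'   quantiles `q05`-`q95`, and the 90%-interval sign flag.
#' @export
tidy.bw_fit <- function(x, ...) x$summary

#' One-row fit overview
#'
#' @param x a `bw_fit`.
#' @param ... unused.
#' @return tibble with observation counts, marginal log-likelihood,
#'   convergence code and (when spatial) the nominal range in km.
#' @export
glance.bw_fit <- function(x, ...) {
  tibble(model = x$model, nobs = x$n, n_sites = x$n_sites,
         marginal_ll = x$marginal_ll,
         converged = x$diagnostics$outer_convergence == 0,
         nominal_range_km = if (!is.null(x$field)) nominal_range(x) else NA_real_)
}

#' Forest plot of fixed-effect posteriors
#'
#' Posterior means with 50% and 90% credibility bars, coloured by the sign of
#' the 90% interval (the model's criterion for a relationship).
#'
#' @param object a `bw_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.bw_fit <- function(object, ...) {
  s <- dplyr::filter(object$summary, .data$term != "(Intercept)")
  s$term <- factor(s$term, levels = rev(s$term))
  s$relationship <- summarize_signs(s)$relationship
  ggplot2::ggplot(s, ggplot2::aes(x = .data$mean, y = .data$term,
                                  colour = .data$relationship)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_linerange(ggplot2::aes(xmin = .data$q05, xmax = .data$q95),
                            linewidth = 0.5) +
    ggplot2::geom_linerange(ggplot2::aes(xmin = .data$q25, xmax = .data$q75),
                            linewidth = 1.4) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(values = c(positive = "#c0392b",
                                            negative = "#2471a3",
                                            none = "grey55")) +
    ggplot2::labs(x = "posterior coefficient (standardized scale)", y = NULL,
                  colour = "90% CI sign") +
    ggplot2::theme_minimal()
}

#' Plot a daily SST series with its threshold and detected events
#'
#' @param series tibble with `date`, `sst`.
#' @param clim climatology from [build_climatology()].
#' @param events events from [detect_events()].
#' @return a ggplot.
#' @export
plot_events <- function(series, clim, events) {
  doy <- pseudo_doy(series$date)
  df <- dplyr::mutate(series, clim_mean = clim$clim_mean[doy],
                      threshold = clim$clim_p90[doy])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$date)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$sst), colour = "grey30") +
    ggplot2::geom_line(ggplot2::aes(y = .data$clim_mean), colour = "#2471a3") +
    ggplot2::geom_line(ggplot2::aes(y = .data$threshold), colour = "#c0392b",
                       linetype = 2) +
    ggplot2::labs(x = NULL, y = "SST (°C)") +
    ggplot2::theme_minimal()
  if (nrow(events)) {
    p <- p + ggplot2::geom_rect(
      data = events, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start_date, xmax = .data$end_date,
                   ymin = -Inf, ymax = Inf),
      fill = "#c0392b", alpha = 0.15)
  }
  p
}

#' Plot the marginal intensity-by-latitude curve
#'
#' @param curve tibble from [marginal_intensity_curve()].
#' @return a ggplot.
#' @export
plot_intensity_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$lat, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "#c0392b", alpha = 0.2) +
    ggplot2::geom_line(colour = "#c0392b") +
    ggplot2::labs(x = "latitude (°)",
                  y = "fitted mean heatwave intensity (°C)") +
    ggplot2::theme_minimal()
}
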