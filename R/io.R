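#' Write / read a truth ledger as YAML
#'
#' Serializes every generating parameter (coefficients, cutpoints, scales,
#' injected events, seed) so a synthetic study can be reproduced or audited.
#' Dates are ISO-8601 strings.
#'
#' @param truth a [truth_ledger()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_truth_yaml <- function(truth, path) {
  x <- unclass(truth)
  x$beta <- as.list(truth$beta)
  x$iid_sds <- as.list(truth$iid_sds)
  if (!is.null(x$injected_events)) {
    ev <- x$injected_events
    ev$start_date <- format(ev$start_date)
    ev$end_date <- format(ev$end_date)
    x$injected_events <- lapply(seq_len(nrow(ev)), function(i) as.list(ev[i, ]))
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_truth_yaml
#' @export
read_truth_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  ev <- NULL
  if (!is.null(x$injected_events)) {
    ev <- dplyr::bind_rows(lapply(x$injected_events, as_tibble))
    ev$start_date <- as.Date(ev$start_date)
    ev$end_date <- as.Date(ev$end_date)
  }
  truth_ledger(beta0 = x$beta0, beta = unlist(x$beta), k1 = x$k1, k2 = x$k2,
               phi = x$phi, spatial_sd = x$spatial_sd,
               spatial_range_km = x$spatial_range_km,
               rw_sd_year = x$rw_sd_year, rw_sd_month = x$rw_sd_month,
               iid_sds = unlist(x$iid_sds), sigma_eps = x$sigma_eps,
               ar1_coef = x$ar1_coef, noise_sd = x$noise_sd,
               injected_events = ev, seed = x$seed)
}
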