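# Small fitted models shared across test files (built lazily, once per run).
.fit_cache <- new.env()

small_truth <- function() truth_ledger()

small_ordbeta_fit <- function() {
  if (is.null(.fit_cache$ob)) {
    sites <- generate_sites(30, seed = 21, n_regions = 10)
    sv <- generate_surveys(sites, small_truth(), n_per_site = 10, seed = 21)
    .fit_cache$ob <- fit_ordered_beta(sv, control = bw_control(outer_maxit = 150))
    .fit_cache$ob_surveys <- sv
  }
  .fit_cache$ob
}

small_gamma_fit <- function() {
  if (is.null(.fit_cache$gm)) {
    sites <- generate_sites(40, seed = 31, n_regions = 12)
    gi <- generate_gamma_intensities(sites, beta0 = 0.6, betaL = 0.3, shape = 2,
                                     seed = 31, n_per_site = 10,
                                     spatial_sd = 0.3, site_sd = 0.15,
                                     rw_sd_year = 0.15, rw_sd_month = 0.1)
    .fit_cache$gm <- fit_gamma_latitude(gi, control = bw_control(outer_maxit = 200))
  }
  .fit_cache$gm
}
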