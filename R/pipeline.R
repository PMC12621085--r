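#' Configuration for an end-to-end pipeline run
#'
#' Collects every window, kernel and threshold constant of the analysis with
#' its standard default (30/60-day covariate windows, 5-day minimum heatwave
#' duration above the 90th percentile, 14-day survey linkage, 0.5-15.5-year
#' historical-frequency window, |r| < 0.6 collinearity screen, 20 m depth
#' cutoff, 20/50 m BPI annulus, 6371 km Earth radius), the synthetic study
#' sizes, and the run seed. The configuration round-trips losslessly through
#' YAML via [write_config()]/[read_config()].
#'
#' @param seed run seed.
#' @param n_sites,n_per_site synthetic study size.
#' @param stages character vector of enabled stages, in order, from
#'   `c("simulate", "detect", "covariates", "fit", "intensity_model", "report")`.
#' @param ... overrides for any default constant (see the returned list).
#' @return a named list of class `bw_config`.
#' @export
pipeline_config <- function(seed = 1L, n_sites = 25, n_per_site = 30,
                            stages = c("simulate", "detect", "covariates",
                                       "fit", "intensity_model", "report"),
                            ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_sites = n_sites, n_per_site = n_per_site,
    stages = stages,
    sst_start = "1985-01-01", sst_end = "2020-12-31",
    baseline_start = "1985-01-01", baseline_end = "2014-12-31",
    clim_window_halfwidth = 5, clim_smooth_width = 31,
    heatwave_percentile = 0.9, min_duration = 5, max_gap = 2,
    link_lag_days = 14, freq_window_years = c(0.5, 15.5),
    temperature_window = 30, irradiance_window = 30, turbidity_window = 60,
    current_window = 30, wave_window = 60,
    collinearity_threshold = 0.6, depth_cutoff_m = 20,
    bpi_inner_m = 20, bpi_outer_m = 50, earth_radius_km = 6371,
    outer_maxit = 300)
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = c("bw_config", "list"))
}

#' @rdname pipeline_config
#' @param config a `bw_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  structure(x, class = c("bw_config", "list"))
}

#' Run the full synthetic pipeline
#'
#' Executes the enabled stages in order — simulate (sites, truth, SST,
#' bathymetry, survey schedule), detect (climatology + heatwave events per
#' site), covariates (windowed means, event linkage, terrain metrics, formula
#' covariates, sampling effort, standardization, collinearity screen), fit
#' (ordered-beta hierarchical model on the chain-computed covariates, with
#' outcomes drawn from the truth ledger), intensity_model (gamma model on the
#' mean intensities of heatwave-linked surveys), report — writing intermediate
#' tables, posterior summaries, a coefficient table, the latent-grid export
#' and a structured run log into `dir`. Any stage failure aborts with the
#' stage name; a disabled upstream stage aborts with the missing artifact.
#'
#' @param config a [pipeline_config()].
#' @param dir output directory (created if needed).
#' @param truth optional [truth_ledger()]; defaults to the standard truth.
#' @return the run directory path, invisibly; the in-memory stage state is
#'   attached as attribute `state`.
#' @export
run_pipeline <- function(config = pipeline_config(), dir = tempfile("bwrun"),
                         truth = NULL) {
  t_start <- Sys.time()
  for (d in file.path(dir, c("", "data", "events", "covariates", "posterior"))) {
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  }
  write_config(config, file.path(dir, "config.yml"))
  truth <- truth %||% truth_ledger(seed = config$seed)
  state <- new.env()
  log_lines <- character(0)
  log_add <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, paste0(format(Sys.time(), "%H:%M:%S "), msg))
  }
  need <- function(what, stage) {
    if (!exists(what, envir = state)) {
      abort(sprintf("stage %s: missing upstream artifact '%s'", stage, what))
    }
    get(what, envir = state)
  }
  run_stage <- function(name, fun) {
    if (!name %in% config$stages) return(invisible(NULL))
    t0 <- Sys.time()
    ok <- tryCatch({ fun(); TRUE }, error = function(e) {
      abort(sprintf("stage %s failed: %s", name, conditionMessage(e)))
    })
    log_add("stage %-15s done in %.1f s", name,
            as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }

  run_stage("simulate", function() {
    sites <- generate_sites(config$n_sites, seed = config$seed)
    keep <- sites$depth <= config$depth_cutoff_m
    log_add("simulate: %d sites, %d dropped by %g m depth cutoff",
            nrow(sites), sum(!keep), config$depth_cutoff_m)
    sites <- sites[keep, ]
    sst <- generate_sst_series(sites, truth, as.Date(config$sst_start),
                               as.Date(config$sst_end),
                               seed = child_seed(config$seed, 1L))
    set.seed(child_seed(config$seed, 2L))
    n <- nrow(sites) * config$n_per_site
    idx <- rep(seq_len(nrow(sites)), each = config$n_per_site)
    sched <- sites[idx, ]
    sched$year <- sample(2003:2020, n, replace = TRUE)
    sched$month <- sample(12L, n, replace = TRUE)
    sched$date <- as.Date(sprintf("%d-%02d-%02d", sched$year, sched$month,
                                  sample(28L, n, replace = TRUE)))
    # per-survey environmental draws and per-site static fields
    sched$irradiance <- 42 - 4 * abs(sched$lat) / 35 + rnorm(n, sd = 4)
    sched$turbidity <- stats::rlnorm(n, log(0.08), 0.5)
    sched$u_current <- rnorm(n, sd = 0.15)
    sched$v_current <- rnorm(n, sd = 0.15)
    sched$hs <- rgamma(n, 2, scale = 0.6)
    sched$coral_cover <- runif(n, 5, 80)
    constituents <- tibble(
      site_id = sites$site_id,
      m2 = abs(rnorm(nrow(sites), 0.5, 0.2)),
      s2 = abs(rnorm(nrow(sites), 0.25, 0.1)),
      k1 = abs(rnorm(nrow(sites), 0.15, 0.06)),
      o1 = abs(rnorm(nrow(sites), 0.10, 0.05)))
    clouds <- tidyr::expand_grid(site_id = sites$site_id, month = 1:12)
    clouds <- dplyr::left_join(clouds, sites[, c("site_id", "lat")], by = "site_id")
    clouds$cloud_frequency <- pmin(pmax(
      45 + 15 * exp(-(clouds$lat / 12)^2) +
        5 * cos(2 * pi * clouds$month / 12) + rnorm(nrow(clouds), sd = 5),
      0), 100)
    patches <- lapply(seq_len(nrow(sites)), function(i) {
      generate_bathymetry_patch(
        sample(c("bump", "depression", "rough", "tilted-plane"), 1),
        seed = child_seed(config$seed, 100L + i))
    })
    state$sites <- sites; state$sst <- sst; state$schedule <- sched
    state$constituents <- constituents; state$clouds <- clouds
    state$patches <- patches
    write.csv(sites, file.path(dir, "data", "sites.csv"), row.names = FALSE)
    write.csv(sst, file.path(dir, "data", "sst_daily.csv"), row.names = FALSE)
    write_truth_yaml(truth, file.path(dir, "data", "truth.yml"))
    log_add("simulate: %d surveys scheduled, %d daily SST rows", n, nrow(sst))
  })

  run_stage("detect", function() {
    sst <- need("sst", "detect")
    sites <- need("sites", "detect")
    by_site <- split(sst, sst$site_id)
    clims <- lapply(by_site, build_climatology,
                    baseline_start = as.Date(config$baseline_start),
                    baseline_end = as.Date(config$baseline_end),
                    window_halfwidth = config$clim_window_halfwidth,
                    smooth_width = config$clim_smooth_width,
                    probs = config$heatwave_percentile)
    events <- lapply(names(by_site), function(sid) {
      ev <- detect_events(by_site[[sid]], clims[[sid]],
                          min_duration = config$min_duration,
                          max_gap = config$max_gap)
      if (nrow(ev)) ev$site_id <- as.integer(sid)
      ev
    })
    names(events) <- names(by_site)
    state$climatologies <- clims
    state$events <- events
    flat <- dplyr::bind_rows(events)
    write.csv(flat[setdiff(names(flat), "daily")],
              file.path(dir, "events", "events.csv"), row.names = FALSE)
    log_add("detect: %d events across %d sites", nrow(flat), length(events))
  })

  run_stage("covariates", function() {
    sched <- need("schedule", "covariates")
    sst <- need("sst", "covariates")
    events <- need("events", "covariates")
    sst_by_site <- split(sst, sst$site_id)

    per_survey <- purrr::map(seq_len(nrow(sched)), function(i) {
      sid <- as.character(sched$site_id[i]); d <- sched$date[i]
      ser <- sst_by_site[[sid]]
      temp <- window_mean(tibble(date = ser$date, value = ser$sst), d,
                          config$temperature_window)
      ex <- link_survey(events[[sid]], d, max_lag_days = config$link_lag_days)
      freq <- historical_frequency(events[[sid]], d,
                                   window_years = config$freq_window_years)
      tibble(temperature = as.numeric(temp),
             cumulative_intensity = ex$cumulative_to_survey,
             heatwave_active = ex$active, event_id = ex$event_id,
             heatwave_frequency = freq)
    })
    cov <- dplyr::bind_cols(sched, dplyr::bind_rows(per_survey))
    cov$current_velocity <- current_speed(cov$u_current, cov$v_current)
    cov$wave_energy <- wave_energy(cov$hs)
    cons <- need("constituents", "covariates")
    cons$tidal_range <- tidal_range(cons$m2, cons$s2, cons$k1, cons$o1)
    cov <- dplyr::left_join(cov, cons[, c("site_id", "tidal_range")],
                            by = "site_id")
    clouds <- need("clouds", "covariates")
    cov <- dplyr::left_join(cov,
                            clouds[, c("site_id", "month", "cloud_frequency")],
                            by = c("site_id", "month"))
    patches <- need("patches", "covariates")
    sites <- need("sites", "covariates")
    terr <- dplyr::bind_rows(purrr::map(seq_along(patches), function(i) {
      tm <- terrain_metrics(patches[[i]], sites$lat[i])
      tm$site_id <- sites$site_id[i]
      tm
    }))
    terr$polar_alignment[is.na(terr$polar_alignment)] <- 0  # flat reefs
    cov <- dplyr::left_join(
      cov, terr[, c("site_id", "slope", "polar_alignment", "rugosity", "bpi")],
      by = "site_id")
    cov$abs_latitude <- abs(cov$lat)
    cov <- sampling_effort(cov)
    cov <- standardize_covariates(cov)
    screen <- collinearity_screen(cov, cols = setdiff(covariate_names(),
                                                      "temperature_irradiance"),
                                  threshold = config$collinearity_threshold)
    log_add("covariates: %d columns retained, %d dropped by |r| >= %.1f screen",
            length(screen$retained), length(screen$dropped),
            config$collinearity_threshold)
    state$covariates <- cov
    state$screen <- screen
    write.csv(cov[setdiff(names(cov), "event_id")],
              file.path(dir, "covariates", "covariates.csv"), row.names = FALSE)
    if (nrow(screen$report)) {
      write.csv(screen$report, file.path(dir, "covariates", "screen_report.csv"),
                row.names = FALSE)
    }
  })

  run_stage("fit", function() {
    cov <- need("covariates", "fit")
    screen <- need("screen", "fit")
    zcols <- paste0("z_", union(screen$retained, "temperature_irradiance"))
    zcols <- intersect(zcols, names(cov))
    z <- as.matrix(cov[zcols])
    sim <- simulate_outcomes(cov, z, truth, seed = child_seed(config$seed, 3L))
    log_add("fit: %d surveys, %d zeros, %d ones", nrow(sim),
            sum(sim$proportion == 0), sum(sim$proportion == 1))
    fit <- fit_ordered_beta(sim, covariates = zcols,
                            control = bw_control(outer_maxit = config$outer_maxit))
    state$surveys <- sim
    state$fit <- fit
    coefs <- fit$summary
    coefs$relationship <- summarize_signs(fit)$relationship
    # coefficient table ordered by posterior mean, largest positive first
    coefs <- dplyr::arrange(coefs, dplyr::desc(.data$mean))
    write.csv(coefs, file.path(dir, "posterior", "coefficients.csv"),
              row.names = FALSE)
    write.csv(fit$hyper, file.path(dir, "posterior", "hyperparameters.csv"),
              row.names = FALSE)
    grid <- tidyr::expand_grid(
      lat = seq(floor(min(cov$lat)), ceiling(max(cov$lat)), by = 4),
      lon = seq(floor(min(cov$lon)), ceiling(max(cov$lon)), by = 4))
    proj <- project_latent(fit, grid)
    write.csv(proj, file.path(dir, "posterior", "latent_grid.csv"),
              row.names = FALSE)
    write.csv(sim[setdiff(names(sim), "event_id")],
              file.path(dir, "data", "surveys.csv"), row.names = FALSE)
  })

  run_stage("intensity_model", function() {
    cov <- need("covariates", "intensity_model")
    events <- need("events", "intensity_model")
    linked <- cov[cov$heatwave_active, ]
    intens <- purrr::map_dbl(seq_len(nrow(linked)), function(i) {
      ev <- events[[as.character(linked$site_id[i])]]
      ev$mean_intensity[ev$event_id == linked$event_id[i]]
    })
    idat <- dplyr::mutate(linked[, c("site_id", "lat", "lon", "year", "month")],
                          intensity = intens)
    log_add("intensity_model: %d heatwave-linked surveys at %d sites",
            nrow(idat), dplyr::n_distinct(idat$site_id))
    gfit <- fit_gamma_latitude(idat,
                               control = bw_control(outer_maxit = config$outer_maxit))
    state$gamma_fit <- gfit
    write.csv(gfit$summary, file.path(dir, "posterior", "gamma_coefficients.csv"),
              row.names = FALSE)
    curve <- marginal_intensity_curve(gfit, seed = config$seed)
    write.csv(curve, file.path(dir, "posterior", "intensity_curve.csv"),
              row.names = FALSE)
  })

  run_stage("report", function() {
    fit <- if (exists("fit", envir = state)) state$fit
    lines <- c(
      "# Pipeline run report", "",
      sprintf("- seed: %d", config$seed),
      sprintf("- R version: %s", getRversion()),
      sprintf("- bleachwave version: %s",
              as.character(utils::packageVersion("bleachwave"))),
      sprintf("- elapsed: %.1f s",
              as.numeric(difftime(Sys.time(), t_start, units = "secs"))),
      "", "## Stage log", "", paste0("    ", log_lines))
    if (!is.null(fit)) {
      sg <- summarize_signs(fit)
      lines <- c(lines, "", "## Fixed-effect relationships", "",
                 sprintf("- %s: %s", sg$term, sg$label))
    }
    writeLines(lines, file.path(dir, "report.md"))
  })

  writeLines(log_lines, file.path(dir, "run.log"))
  out <- dir
  attr(out, "state") <- state
  invisible(out)
}
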