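#' Windowed mean of a daily series before a survey
#'
#' Mean over the `window_days` days ending the day before the survey (the
#' convention for temperature, irradiance, turbidity and currents) or ending
#' on the survey day itself when `include_survey_day = TRUE` (the wave-energy
#' convention). Missing days are tolerated: the mean uses available days only,
#' and the result is `NA` when fewer than `min_coverage` of the window's days
#' are available. The number of missing days is attached as attribute
#' `n_missing`.
#'
#' @param series tibble with `date` and `value` (daily).
#' @param survey_date a Date.
#' @param window_days window length in days, `>= 1`.
#' @param include_survey_day should the window end on the survey day?
#' @param min_coverage minimum fraction of non-missing days.
#' @return scalar mean with attributes `n_available` and `n_missing`.
#' @export
window_mean <- function(series, survey_date, window_days,
                        include_survey_day = FALSE, min_coverage = 0.25) {
  stopifnot_scalar_date(survey_date, "survey_date")
  if (window_days < 1) abort("`window_days` must be >= 1")
  end <- if (include_survey_day) survey_date else survey_date - 1
  start <- end - window_days + 1
  vals <- series$value[series$date >= start & series$date <= end]
  vals <- vals[!is.na(vals)]
  n_avail <- length(vals)
  out <- if (n_avail >= min_coverage * window_days && n_avail > 0) {
    mean(vals)
  } else {
    NA_real_
  }
  structure(out, n_available = n_avail, n_missing = window_days - n_avail)
}

#' Surface-current speed from velocity components
#'
#' Euclidean magnitude `sqrt(u^2 + v^2)` of the eastward (`u`) and northward
#' (`v`) components; daily magnitudes are averaged over the 30-day window by
#' [window_mean()].
#'
#' @param u,v m/s, vectorized.
#' @return speed, m/s.
#' @export
current_speed <- function(u, v) sqrt(u^2 + v^2)

#' Wave-energy density from significant wave height
#'
#' `E = rho * g * Hs^2 / 8` with seawater density `rho` = 1025 kg/m^3 and
#' `g` = 9.81 m/s^2, where `Hs` is the windowed mean significant wave height.
#'
#' @param hs significant wave height, m, `>= 0`.
#' @param rho seawater density, kg/m^3.
#' @param g gravitational acceleration, m/s^2.
#' @return energy density, J/m^2.
#' @export
wave_energy <- function(hs, rho = 1025, g = 9.81) {
  if (any(hs < 0, na.rm = TRUE)) abort("`hs` must be >= 0")
  0.125 * rho * g * hs^2
}

#' Tidal range from the four principal constituent amplitudes
#'
#' `R = 2 * (M2 + S2 + K1 + O1)`: twice the sum of the principal
#' lunar-semidiurnal, solar-semidiurnal, lunisolar-diurnal and lunar-diurnal
#' amplitudes.
#'
#' @param m2,s2,k1,o1 constituent amplitudes, m, `>= 0`.
#' @return tidal range, m/day.
#' @export
tidal_range <- function(m2, s2, k1, o1) {
  if (any(c(m2, s2, k1, o1) < 0, na.rm = TRUE)) {
    abort("constituent amplitudes must be >= 0")
  }
  2 * (m2 + s2 + k1 + o1)
}

#' Sampling effort per ecoregion-month-year cell
#'
#' Each survey receives the count of surveys sharing its ecoregion, calendar
#' month and year (a proxy for detection effort / sampling bias).
#'
#' @param surveys tibble with `ecoregion_id` and either `date` or both `year`
#'   and `month`.
#' @return the input with a `sampling_effort` column appended.
#' @export
sampling_effort <- function(surveys) {
  if (!"ecoregion_id" %in% names(surveys)) abort("`ecoregion_id` column required")
  s <- surveys
  if (!all(c("year", "month") %in% names(s))) {
    if (!"date" %in% names(s)) abort("need `date` or `year` + `month` columns")
    s$year <- date_year(s$date)
    s$month <- date_month(s$date)
  }
  key <- paste(s$ecoregion_id, s$year, s$month)
  surveys$sampling_effort <- as.numeric(ave(seq_along(key), key, FUN = length))
  surveys
}

#' Standardize covariates and build the temperature-irradiance interaction
#'
#' Z-scores each raw column (subtract mean, divide by sd) and constructs the
#' interaction as the product of the standardized temperature and irradiance
#' columns, without re-standardizing the product. Column means and sds are
#' stored in attribute `scaling` so new data can be placed on the same scale.
#'
#' @param data tibble containing the raw covariate columns.
#' @param cols character vector of columns to standardize (default: all of
#'   [covariate_names()] except the interaction, intersected with `data`).
#' @param interaction build `z_temperature_irradiance` from `z_temperature *
#'   z_irradiance` when both are present?
#' @return `data` with `z_<name>` columns appended; attribute `scaling` is a
#'   tibble of per-column means and sds.
#' @export
standardize_covariates <- function(data, cols = NULL, interaction = TRUE) {
  if (is.null(cols)) {
    cols <- intersect(setdiff(covariate_names(), "temperature_irradiance"),
                      names(data))
  }
  if (!length(cols)) abort("no covariate columns found")
  mus <- vapply(cols, function(cl) mean(data[[cl]], na.rm = TRUE), numeric(1))
  sds <- vapply(cols, function(cl) sd(data[[cl]], na.rm = TRUE), numeric(1))
  bad <- cols[!is.finite(sds) | sds == 0]
  if (length(bad)) {
    abort(paste0("zero-variance covariate column(s): ", paste(bad, collapse = ", ")))
  }
  for (cl in cols) {
    data[[paste0("z_", cl)]] <- (data[[cl]] - mus[[cl]]) / sds[[cl]]
  }
  if (interaction && all(c("z_temperature", "z_irradiance") %in% names(data))) {
    data$z_temperature_irradiance <- data$z_temperature * data$z_irradiance
  }
  attr(data, "scaling") <- tibble(column = cols, mean = unname(mus), sd = unname(sds))
  data
}

#' Screen covariates for collinearity
#'
#' Computes pairwise Pearson correlations and iteratively drops the column
#' with the largest mean absolute correlation to all remaining columns until
#' every pairwise |r| is below `threshold` (default 0.6). The report lists all
#' offending pairs of the input.
#'
#' @param data tibble of raw covariates.
#' @param cols columns to screen (default: all numeric columns).
#' @param threshold retention threshold on |r|.
#' @return list with `retained` (character), `dropped` (character), and
#'   `report` (tibble of pairs with |r| >= threshold in the input).
#' @export
collinearity_screen <- function(data, cols = NULL, threshold = 0.6) {
  if (is.null(cols)) cols <- names(data)[vapply(data, is.numeric, logical(1))]
  if (length(cols) < 2) abort("need at least two columns to screen")
  cm <- suppressWarnings(cor(data[cols], use = "pairwise.complete.obs"))
  cm[!is.finite(cm)] <- 0
  pairs <- which(abs(cm) >= threshold & upper.tri(cm), arr.ind = TRUE)
  report <- tibble(var1 = cols[pairs[, 1]], var2 = cols[pairs[, 2]],
                   r = cm[pairs])
  keep <- cols
  repeat {
    sub <- abs(cm[keep, keep, drop = FALSE])
    diag(sub) <- 0
    if (length(keep) < 2 || max(sub) < threshold) break
    worst <- keep[which.max(rowMeans(sub))]
    keep <- setdiff(keep, worst)
  }
  list(retained = keep, dropped = setdiff(cols, keep), report = report)
}
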