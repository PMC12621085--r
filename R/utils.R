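# Internal helpers shared across modules.

# log(1 + exp(x)) without overflow
log1pexp <- function(x) {
  out <- x
  small <- x <= 18
  out[small] <- log1p(exp(x[small]))
  mid <- x > 18 & x <= 33.3
  out[mid] <- x[mid] + exp(-x[mid])
  out
}

# hemisphere label; the Equator itself is counted as northern
hemisphere_of <- function(lat) ifelse(lat >= 0, "north", "south")

date_year <- function(date) as.integer(format(date, "%Y"))
date_month <- function(date) as.integer(format(date, "%m"))

# day-of-year on a fixed non-leap calendar; Feb 29 is folded to day 366
pseudo_doy <- function(date) {
  lt <- as.POSIXlt(date)
  mon <- lt$mon + 1L
  mday <- lt$mday
  cum <- c(0L, 31L, 59L, 90L, 120L, 151L, 181L, 212L, 243L, 273L, 304L, 334L)
  doy <- cum[mon] + mday
  doy[mon == 2L & mday == 29L] <- 366L
  # days after Feb in leap years keep their non-leap day number by construction
  doy
}

stopifnot_scalar_date <- function(x, name) {
  if (!inherits(x, "Date") || length(x) != 1L || is.na(x)) {
    abort(paste0("`", name, "` must be a single non-missing Date"))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic child seed streams derived from one integer seed
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 16807) %% 2147483562)
}
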