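# Terrain metrics from small bathymetry patches (positive-down depths,
# rows north -> south, columns west -> east, fixed cell spacing).

patch_depths <- function(patch) {
  if (inherits(patch, "bw_patch")) patch$depths else as.matrix(patch)
}

patch_cell <- function(patch, default = 10) {
  if (inherits(patch, "bw_patch")) patch$cell_m else default
}

check_neighborhood <- function(depths, focal, margin) {
  if (focal[1] - margin < 1 || focal[1] + margin > nrow(depths) ||
      focal[2] - margin < 1 || focal[2] + margin > ncol(depths)) {
    abort("focal neighborhood extends outside the patch")
  }
}

#' Slope, aspect and northness from a 3x3 queen kernel
#'
#' Depths are first negated (so values decrease downslope, the terrestrial
#' convention), then Horn's weighted finite differences over the 8 queen
#' neighbours estimate the surface gradient: edge neighbours weigh 2, corner
#' neighbours 1, divisor `8 * cell size`. Slope is `atan` of the gradient
#' magnitude in degrees (0 = parallel to the sea surface); aspect is the
#' downslope compass bearing (0 = north, 90 = east), undefined (`NA`) on flat
#' neighbourhoods; northness is `cos(aspect)`, southness its negative.
#'
#' @param patch a `bw_patch` or a depth matrix (m, positive down).
#' @param focal `c(row, col)` of the focal cell (1-based; default the centre
#'   of a 7x7 patch).
#' @return one-row tibble: `slope`, `aspect`, `northness`, `southness`.
#' @export
slope_aspect <- function(patch, focal = c(4, 4)) {
  depths <- patch_depths(patch)
  h <- patch_cell(patch)
  check_neighborhood(depths, focal, 1)
  z <- -depths  # elevation convention
  r <- focal[1]; c0 <- focal[2]
  gx <- ((z[r - 1, c0 + 1] + 2 * z[r, c0 + 1] + z[r + 1, c0 + 1]) -
         (z[r - 1, c0 - 1] + 2 * z[r, c0 - 1] + z[r + 1, c0 - 1])) / (8 * h)
  gy <- ((z[r - 1, c0 - 1] + 2 * z[r - 1, c0] + z[r - 1, c0 + 1]) -
         (z[r + 1, c0 - 1] + 2 * z[r + 1, c0] + z[r + 1, c0 + 1])) / (8 * h)
  slope <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  if (gx == 0 && gy == 0) {
    aspect <- NA_real_
    northness <- NA_real_
  } else {
    aspect <- (atan2(-gx, -gy) * 180 / pi) %% 360
    northness <- cos(aspect * pi / 180)
  }
  tibble(slope = slope, aspect = aspect,
         northness = northness, southness = -northness)
}

#' Polar alignment of the reef aspect
#'
#' Northness for northern-hemisphere sites, southness for southern-hemisphere
#' sites: positive values face away from the Equator, negative values toward
#' it.
#'
#' @param northness in \[-1, 1\] (possibly `NA` for flat reefs).
#' @param lat site latitude, degrees.
#' @return value in \[-1, 1\].
#' @export
polar_alignment <- function(northness, lat) {
  ifelse(lat >= 0, northness, -northness)
}

#' Rugosity: residual standard deviation around a local OLS plane
#'
#' Fits an ordinary least-squares plane to the 3x3 neighbourhood of the focal
#' cell and returns the standard deviation (divisor `n - 1` by default) of the
#' residual depths. Zero for flat reefs and for any exactly planar surface.
#'
#' @inheritParams slope_aspect
#' @param sample_sd use the `n - 1` divisor (`FALSE` for population sd).
#' @return rugosity in m, `>= 0`.
#' @export
rugosity <- function(patch, focal = c(4, 4), sample_sd = TRUE) {
  depths <- patch_depths(patch)
  h <- patch_cell(patch)
  check_neighborhood(depths, focal, 1)
  rows <- (focal[1] - 1):(focal[1] + 1)
  cols <- (focal[2] - 1):(focal[2] + 1)
  d <- as.vector(depths[rows, cols])
  xy <- expand.grid(y = rows, x = cols)  # column-major to match as.vector
  X <- cbind(1, xy$x * h, xy$y * h)
  res <- d - X %*% solve(crossprod(X), crossprod(X, d))
  if (sample_sd) sd(res) else sqrt(mean((res - mean(res))^2))
}

#' Bathymetric-position index from an annulus kernel
#'
#' Mean depth of the annulus cells (centre distance between `inner_m` and
#' `outer_m` from the focal cell, inclusive) minus the focal depth, computed
#' on positive-down depths. Positive values mark habitats shallower than their
#' surroundings (crests, patch reefs); negative values mark deeper habitats
#' (channels, lagoons). On a 7x7 patch at 10 m spacing the 50 m outer radius
#' truncates at the corners, which is accepted.
#'
#' @inheritParams slope_aspect
#' @param inner_m,outer_m annulus radii, m.
#' @return BPI in m.
#' @export
bpi <- function(patch, focal = c(4, 4), inner_m = 20, outer_m = 50) {
  depths <- patch_depths(patch)
  h <- patch_cell(patch)
  ri <- row(depths) - focal[1]
  ci <- col(depths) - focal[2]
  dist <- h * sqrt(ri^2 + ci^2)
  ann <- dist >= inner_m & dist <= outer_m
  if (!any(ann)) abort("annulus contains no cells")
  mean(depths[ann]) - depths[focal[1], focal[2]]
}

#' All topographic metrics for one site
#'
#' Convenience wrapper combining [slope_aspect()], [polar_alignment()],
#' [rugosity()] and [bpi()] for a site's bathymetry patch.
#'
#' @inheritParams slope_aspect
#' @param lat site latitude (for polar alignment).
#' @return one-row tibble with `slope`, `aspect`, `northness`,
#'   `polar_alignment`, `rugosity`, `bpi`.
#' @export
terrain_metrics <- function(patch, lat, focal = c(4, 4)) {
  sa <- slope_aspect(patch, focal)
  tibble(slope = sa$slope, aspect = sa$aspect, northness = sa$northness,
         polar_alignment = polar_alignment(sa$northness, lat),
         rugosity = rugosity(patch, focal),
         bpi = bpi(patch, focal))
}
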