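#' Density profile object
#'
#' An eccentricity-ordered series of densities (or intercone distances)
#' around the CDC.
#'
#' @param eccentricity Strictly ordered eccentricities (um).
#' @param density Values per bin (cones/mm^2, or um for ICD profiles).
#' @param kind Profile kind, e.g. `"horizontal"`, `"vertical"`, `"nasal"`,
#'   `"temporal"`, `"superior"`, `"inferior"`, `"radial"`, `"icd"`.
#' @param bin_width Eccentricity bin width (um).
#' @param normalized Whether densities have been divided by a reference D0.
#' @param d0_ref The D0 used for normalization (`NA` if unnormalized).
#' @return An object of class `density_profile`.
#' @export
density_profile <- function(eccentricity, density, kind = "radial",
                            bin_width = NA_real_, normalized = FALSE,
                            d0_ref = NA_real_) {
  if (length(eccentricity) != length(density))
    stop("eccentricity and density must have equal length")
  if (is.unsorted(eccentricity, strictly = TRUE))
    stop("eccentricity must be strictly increasing")
  structure(list(eccentricity = as.numeric(eccentricity),
                 density = as.numeric(density), kind = kind,
                 bin_width = bin_width, normalized = normalized,
                 d0_ref = d0_ref),
            class = "density_profile")
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("%s density profile: %d bins, E in [%g, %g] um%s\n",
              x$kind, length(x$eccentricity), min(x$eccentricity),
              max(x$eccentricity),
              if (x$normalized) sprintf(" (normalized by D0 = %.0f)", x$d0_ref)
              else ""))
  invisible(x)
}

#' @export
as.data.frame.density_profile <- function(x, ...) {
  data.frame(eccentricity = x$eccentricity, density = x$density)
}

# map angle in retinal convention (0 = nasal, 90 = superior) to an angle in
# map coordinates; the x-axis is mirrored for right eyes so that fellow
# eyes are comparable in retinal coordinates
retinal_to_map_angle <- function(theta_deg, laterality) {
  if (identical(laterality, "OD")) (180 - theta_deg) %% 360 else theta_deg %% 360
}

#' Meridional density profile within a triangular sector
#'
#' Average density per eccentricity bin inside an isosceles triangle sector
#' with its vertex at the CDC. `direction` is in retinal convention (0 =
#' nasal, 90 = superior retina); for the full-meridian kinds
#' (`"horizontal"`, `"vertical"`) the two opposite sectors are pooled per
#' absolute eccentricity.
#'
#' @param map A `density_map`.
#' @param cdc CDC location `(x, y)` in um.
#' @param direction Sector direction in degrees (retinal convention), or one
#'   of `"nasal"` (0), `"temporal"` (180), `"superior"` (90), `"inferior"`
#'   (270), `"horizontal"`, `"vertical"`.
#' @param vertex_angle Full sector vertex angle (degrees), default 5.
#' @param bin_width Eccentricity bin width (um); defaults to the grid
#'   spacing.
#' @return A [density_profile]; bins with no valid map point are absent.
#' @export
meridional_profile <- function(map, cdc, direction = "horizontal",
                               vertex_angle = 5, bin_width = NULL) {
  stopifnot(inherits(map, "density_map"))
  bin_width <- bin_width %||% map$spacing
  named <- c(nasal = 0, temporal = 180, superior = 90, inferior = 270)
  if (is.character(direction)) {
    kind <- direction
    dirs <- switch(direction,
                   horizontal = c(0, 180), vertical = c(90, 270),
                   nasal = 0, temporal = 180, superior = 90, inferior = 270,
                   stop("unknown direction: ", direction))
  } else {
    kind <- sprintf("sector_%g", direction)
    dirs <- direction
  }
  dirs_map <- retinal_to_map_angle(dirs, map$laterality)
  if (cdc[1] < min(map$x) || cdc[1] > max(map$x) ||
      cdc[2] < min(map$y) || cdc[2] > max(map$y))
    stop("CDC lies outside the density map")
  gx <- rep(map$x, times = length(map$y))
  gy <- rep(map$y, each = length(map$x))
  v <- as.vector(map$values)
  ok <- is.finite(v)
  gx <- gx[ok] - cdc[1]; gy <- gy[ok] - cdc[2]; v <- v[ok]
  E <- sqrt(gx^2 + gy^2)
  ang <- (atan2(gy, gx) * 180 / pi) %% 360
  insec <- Reduce(`|`, lapply(dirs_map, function(d)
    ang_diff(ang, d) <= vertex_angle / 2)) | E < 1e-9
  E <- E[insec]; v <- v[insec]
  if (!length(E)) stop("no valid map points inside the sector")
  bin <- round(E / bin_width)
  agg <- tapply(v, bin, mean)
  ecc <- as.numeric(names(agg)) * bin_width
  o <- order(ecc)
  density_profile(ecc[o], as.numeric(agg)[o], kind = kind,
                  bin_width = bin_width)
}

#' Radially averaged density profile
#'
#' For each eccentricity, the mean of map densities sampled on the circle of
#' that radius centered at the CDC (bilinear interpolation at 1-degree
#' steps). The value at eccentricity 0 is the map density at the CDC. The
#' profile is truncated at the largest eccentricity whose full circle lies
#' in the valid map region.
#'
#' @param map A `density_map`.
#' @param cdc CDC location `(x, y)` in um.
#' @param max_ecc Largest eccentricity to attempt (um); defaults to the
#'   distance from the CDC to the nearest map edge.
#' @param step Eccentricity step (um); defaults to the grid spacing.
#' @param angular_step Angular sampling step (degrees), default 1.
#' @return A [density_profile] of kind `"radial"`.
#' @export
radial_profile <- function(map, cdc, max_ecc = NULL, step = NULL,
                           angular_step = 1) {
  stopifnot(inherits(map, "density_map"))
  step <- step %||% map$spacing
  max_ecc <- max_ecc %||% min(cdc[1] - min(map$x), max(map$x) - cdc[1],
                              cdc[2] - min(map$y), max(map$y) - cdc[2])
  d0 <- map_interp(map, cdc[1], cdc[2])
  if (is.na(d0)) stop("CDC lies outside the valid map region")
  th <- deg2rad(seq(0, 360 - angular_step, by = angular_step))
  ecc <- seq(step, max_ecc, by = step)
  dens <- rep(NA_real_, length(ecc))
  for (i in seq_along(ecc)) {
    s <- map_interp(map, cdc[1] + ecc[i] * cos(th), cdc[2] + ecc[i] * sin(th))
    if (anyNA(s)) break
    dens[i] <- mean(s)
  }
  keep <- !is.na(dens)
  density_profile(c(0, ecc[keep]), c(d0, dens[keep]), kind = "radial",
                  bin_width = step)
}

#' Normalize a density profile by D0
#'
#' @param profile A [density_profile] (not already normalized).
#' @param d0 Central density (cones/mm^2), `> 0`.
#' @return The normalized [density_profile].
#' @export
normalize_profile <- function(profile, d0) {
  stopifnot(inherits(profile, "density_profile"))
  if (isTRUE(profile$normalized))
    stop("profile is already normalized")
  stop_if_not_number(d0, "d0", lower = 0, strict_lower = TRUE)
  density_profile(profile$eccentricity, profile$density / d0,
                  kind = profile$kind, bin_width = profile$bin_width,
                  normalized = TRUE, d0_ref = d0)
}

#' Circular density profile at fixed eccentricity
#'
#' Density sampled by bilinear interpolation around the circle of a given
#' eccentricity centered at the CDC. Angles follow the retinal convention
#' (theta 0 = nasal, 90 = superior retina), mapped through the eye's
#' laterality. Circles that exit the valid map region are rejected.
#'
#' @param map A `density_map`.
#' @param cdc CDC location `(x, y)` in um.
#' @param eccentricity Circle radius (um).
#' @param angular_step Angular step (degrees), default 1.
#' @return An object of class `circular_profile` with fields `eccentricity`,
#'   `theta` (degrees in \[0, 360)), `density`, `normalized`.
#' @export
circular_profile <- function(map, cdc, eccentricity, angular_step = 1) {
  stopifnot(inherits(map, "density_map"))
  stop_if_not_number(eccentricity, "eccentricity", lower = 0,
                     strict_lower = TRUE)
  theta <- seq(0, 360 - angular_step, by = angular_step)
  th_map <- deg2rad(retinal_to_map_angle(theta, map$laterality))
  v <- map_interp(map, cdc[1] + eccentricity * cos(th_map),
                  cdc[2] + eccentricity * sin(th_map))
  if (anyNA(v))
    stop(sprintf("circle at eccentricity %g um exits the valid map region",
                 eccentricity))
  structure(list(eccentricity = eccentricity, theta = theta, density = v,
                 normalized = FALSE),
            class = "circular_profile")
}

#' @export
print.circular_profile <- function(x, ...) {
  cat(sprintf("Circular profile at E = %g um: %d angular samples, CV = %.2f%%\n",
              x$eccentricity, length(x$theta),
              100 * stats::sd(x$density) / mean(x$density)))
  invisible(x)
}

#' Intercone distance profile
#'
#' Per-cone intercone distance (ICD) is the mean distance to the cone's
#' Voronoi (Delaunay) neighbors; hull cones with unbounded cells are
#' excluded. ICDs are binned by eccentricity from the CDC and smoothed by a
#' centered moving mean of 11 um (truncated at the domain ends).
#'
#' @param mosaic A [cone_mosaic] with at least 150 cones.
#' @param cdc CDC location `(x, y)` in um.
#' @param bin_width Eccentricity bin width (um), default 1.
#' @param smooth_window Moving-mean window (um), default 11.
#' @return A [density_profile] of kind `"icd"` whose values are ICDs in um.
#' @export
intercone_distance_profile <- function(mosaic, cdc = c(0, 0), bin_width = 1,
                                       smooth_window = 11) {
  stopifnot(inherits(mosaic, "cone_mosaic"))
  if (n_cones(mosaic) < 150) stop("at least 150 cones are required")
  cells <- voronoi_cell_areas(mosaic)
  dd <- deldir::deldir(mosaic$x, mosaic$y)
  del <- dd$delsgs
  len <- sqrt((del$x1 - del$x2)^2 + (del$y1 - del$y2)^2)
  n <- n_cones(mosaic)
  tot <- rep(0, n); cnt <- rep(0L, n)
  for (side in 1:2) {
    ind <- if (side == 1) del$ind1 else del$ind2
    tt <- tapply(len, ind, sum); cc <- tapply(len, ind, length)
    ii <- as.integer(names(tt))
    tot[ii] <- tot[ii] + as.numeric(tt)
    cnt[ii] <- cnt[ii] + as.integer(cc)
  }
  icd <- tot / cnt
  keep <- !cells$unbounded & cnt > 0
  E <- sqrt((mosaic$x - cdc[1])^2 + (mosaic$y - cdc[2])^2)[keep]
  icd <- icd[keep]
  bin <- round(E / bin_width)
  agg <- tapply(icd, bin, mean)
  ecc <- as.numeric(names(agg)) * bin_width
  o <- order(ecc)
  ecc <- ecc[o]; val <- as.numeric(agg)[o]
  # centered moving mean over a window of smooth_window um, truncated at ends
  half <- floor(smooth_window / bin_width / 2)
  sm <- vapply(seq_along(val), function(i) {
    lo <- max(1, i - half); hi <- min(length(val), i + half)
    mean(val[lo:hi])
  }, numeric(1))
  density_profile(ecc, sm, kind = "icd", bin_width = bin_width)
}

#' Convert between linear and angular retinal units
#'
#' Exact arithmetic conversions using the retinal magnification factor:
#' lengths um <-> degrees divide/multiply by `rmf`; densities
#' cones/mm^2 <-> cones/deg^2 use `(rmf / 1000)^2`.
#'
#' @param value Numeric value(s).
#' @param from,to Units: `"um"`, `"deg"`, `"cones_per_mm2"`,
#'   `"cones_per_deg2"`.
#' @param rmf Retinal magnification factor (um/degree), `> 0`.
#' @return Converted value(s).
#' @examples
#' convert_units(1, "deg", "um", rmf = 291)          # 291 um
#' convert_units(175500, "cones_per_mm2", "cones_per_deg2", rmf = 291)
#' @export
convert_units <- function(value, from, to, rmf) {
  stop_if_not_number(rmf, "rmf", lower = 0, strict_lower = TRUE)
  units <- c("um", "deg", "cones_per_mm2", "cones_per_deg2")
  from <- match.arg(from, units); to <- match.arg(to, units)
  if (from == to) return(value)
  key <- paste(from, to)
  switch(key,
    "um deg" = value / rmf,
    "deg um" = value * rmf,
    "cones_per_mm2 cones_per_deg2" = value * (rmf / 1000)^2,
    "cones_per_deg2 cones_per_mm2" = value / (rmf / 1000)^2,
    stop(sprintf("unsupported conversion: %s -> %s", from, to)))
}

#' Maximum slope and inflection point of a fitted density profile
#'
#' Numerically differentiates the fitted sigmoid model (0.01 um step) and
#' reports the most negative slope and the eccentricity at which it occurs.
#' A [density_profile] input is first fitted with [fit_profile()].
#'
#' @param x A [sigmoid_params], `fit_result`, or [density_profile] (dense
#'   enough to fit: at least 10 bins).
#' @param e_max Upper end of the scanned eccentricity range (um).
#' @param step Differentiation step (um), default 0.01.
#' @return List with `max_slope` ((cones/mm^2)/um, negative) and
#'   `inflection` (um).
#' @export
profile_slope_metrics <- function(x, e_max = 500, step = 0.01) {
  params <- if (inherits(x, "sigmoid_params")) x
  else if (inherits(x, "fit_result")) x$params
  else if (inherits(x, "density_profile")) fit_profile(x)$params
  else stop("x must be sigmoid_params, fit_result, or density_profile")
  E <- seq(0, e_max, by = step)
  D <- evaluate_model(params, E)
  d <- diff(D) / step
  i <- which.min(d)
  list(max_slope = d[i], inflection = E[i] + step / 2)
}
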