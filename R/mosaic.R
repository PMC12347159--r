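#' Cone mosaic object
#'
#' Planar cone center coordinates (um, arbitrary origin) plus per-eye
#' metadata. This is the universal input of the analysis pipeline, standing
#' in for a fully annotated foveal montage.
#'
#' @param x,y Numeric vectors of cone center coordinates (um).
#' @param rmf Retinal magnification factor (um per degree of visual angle).
#' @param laterality `"OS"` (left eye), `"OD"` (right eye) or `"synthetic"`.
#' @param occlusion_radius Radius (um) of a central occluded disk, or `NULL`.
#' @param provenance Free-text provenance string.
#' @return An object of class `cone_mosaic`.
#' @export
cone_mosaic <- function(x, y, rmf = 291, laterality = "synthetic",
                        occlusion_radius = NULL, provenance = "") {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("cone coordinates must be finite")
  if (anyDuplicated(cbind(x, y)))
    stop("duplicate cone coordinates are not allowed")
  stop_if_not_number(rmf, "rmf", lower = 0, strict_lower = TRUE)
  laterality <- match.arg(laterality, c("OS", "OD", "synthetic"))
  if (!is.null(occlusion_radius))
    stop_if_not_number(occlusion_radius, "occlusion_radius", lower = 0)
  structure(list(x = as.numeric(x), y = as.numeric(y), rmf = rmf,
                 laterality = laterality,
                 occlusion_radius = occlusion_radius,
                 provenance = provenance),
            class = "cone_mosaic")
}

#' @export
print.cone_mosaic <- function(x, ...) {
  cat(sprintf("Cone mosaic: %d cones, rmf = %g um/deg, laterality = %s\n",
              length(x$x), x$rmf, x$laterality))
  if (!is.null(x$occlusion_radius))
    cat(sprintf("  central occlusion radius: %g um\n", x$occlusion_radius))
  invisible(x)
}

n_cones <- function(mosaic) length(mosaic$x)

#' Configuration of the synthetic mosaic generator
#'
#' Describes the target cone-density field of a synthetic mosaic: an
#' anisotropic sigmoid decay whose shape triplet interpolates between a
#' horizontal and a vertical meridian triplet (cos^2-weighted), optionally
#' modulated in angle by an `exp(k cos 2theta)`-shaped rugosity factor.
#' Defaults are the group-average normative meridional fit parameters
#' (see [normative_params()]).
#'
#' @param d0 Central cone density (cones/mm^2).
#' @param params_horizontal,params_vertical [sigmoid_params] giving the
#'   meridional shape triplets (their own `d0` fields are ignored; `d0`
#'   above is used).
#' @param rugosity_amplitude Angular modulation strength `k >= 0` (unitless);
#'   0 disables modulation.
#' @param rugosity_exponent Exponent applied to the modulation (unitless);
#'   together with the amplitude it sets the peak/trough width asymmetry.
#' @param field_radius Radius (um) of the generated field.
#' @param jitter_sd Isotropic Gaussian annotation jitter per cone (um).
#' @param seed Integer RNG seed; identical config + seed reproduces the
#'   mosaic bit-identically.
#' @param rmf Retinal magnification factor (um/degree) stored as metadata.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(d0 = 175500,
                             params_horizontal = normative_params("horizontal"),
                             params_vertical = normative_params("vertical"),
                             rugosity_amplitude = 0,
                             rugosity_exponent = 1,
                             field_radius = 300,
                             jitter_sd = 0.25,
                             seed = 1L,
                             rmf = 291) {
  stop_if_not_number(d0, "d0", lower = 0, strict_lower = TRUE)
  stopifnot(inherits(params_horizontal, "sigmoid_params"),
            inherits(params_vertical, "sigmoid_params"))
  stop_if_not_number(rugosity_amplitude, "rugosity_amplitude", lower = 0)
  stop_if_not_number(rugosity_exponent, "rugosity_exponent")
  stop_if_not_number(field_radius, "field_radius", lower = 0,
                     strict_lower = TRUE)
  stop_if_not_number(jitter_sd, "jitter_sd", lower = 0)
  stop_if_not_number(rmf, "rmf", lower = 0, strict_lower = TRUE)
  structure(list(d0 = d0,
                 params_horizontal = params_horizontal,
                 params_vertical = params_vertical,
                 rugosity_amplitude = rugosity_amplitude,
                 rugosity_exponent = rugosity_exponent,
                 field_radius = field_radius,
                 jitter_sd = jitter_sd,
                 seed = as.integer(seed),
                 rmf = rmf),
            class = "generator_config")
}

#' Target cone density of the synthetic field
#'
#' Evaluates the prescribed two-dimensional density field
#' `D0 * f(E; a(theta), b(theta), c(theta)) * g(theta)` where `f` is the
#' sigmoid decay, the shape triplet interpolates between the horizontal and
#' vertical meridional triplets with cos^2(theta) weights, and
#' `g(theta) = exp(k * cos 2theta)^m` normalized so that its angular mean is
#' one (the normalizer is the modified Bessel function `I0(k m)`). The value
#' at the origin is exactly `D0`.
#'
#' @param x,y Coordinates (um) relative to the field center; vectorized.
#' @param config A [generator_config].
#' @return Density (cones/mm^2) at each point.
#' @export
target_density <- function(x, y, config) {
  stopifnot(inherits(config, "generator_config"))
  E <- sqrt(x^2 + y^2)
  th <- atan2(y, x)
  w <- cos(th)^2
  ph <- config$params_horizontal; pv <- config$params_vertical
  a <- w * ph$a + (1 - w) * pv$a
  b <- w * ph$b + (1 - w) * pv$b
  cc <- w * ph$c + (1 - w) * pv$c
  f <- 1 / (1 + (E / a)^b)^cc
  k <- config$rugosity_amplitude * config$rugosity_exponent
  g <- if (k == 0) 1 else exp(k * cos(2 * th)) / besselI(k, 0)
  d <- config$d0 * f * g
  d[E == 0] <- config$d0
  d
}

# Angular table of the cumulative radial mass integral
# M(r, theta) = int_0^r D(s, theta) s ds (cones per radian), used to warp a
# uniform hexagonal lattice onto the target field.
mass_table <- function(config, r_max, dr = 0.5, dth = 1) {
  th <- seq(0, 360, by = dth)           # closed: column 361 == column 1
  r <- seq(0, r_max, by = dr)
  M <- matrix(0, nrow = length(r), ncol = length(th))
  for (j in seq_along(th)) {
    tr <- deg2rad(th[j])
    dens <- target_density(r * cos(tr), r * sin(tr), config) / 1e6  # per um^2
    f <- dens * r
    M[, j] <- c(0, cumsum((f[-1] + f[-length(f)]) / 2 * dr))
  }
  list(r = r, theta = th, M = M)
}

#' Generate a synthetic cone mosaic
#'
#' Produces a quasi-hexagonal cone point pattern whose local density follows
#' [target_density()]. A uniform hexagonal lattice (density `D0`, random
#' seeded rotation and offset) is warped radially so that the cumulative
#' radial cone mass along every ray matches the target field; the warp is
#' area-true, so local density is preserved exactly while the arrangement
#' stays close to hexagonal. Annotation jitter is added afterwards as
#' isotropic Gaussian displacement.
#'
#' @param config A [generator_config].
#' @return A [cone_mosaic] with all cones inside the disk of
#'   `config$field_radius`, deterministic given `config$seed`.
#' @export
generate_mosaic <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  R <- config$field_radius
  mt <- mass_table(config, r_max = R)
  # expected total count: angular mean of M(R, theta) times 2*pi
  expected <- 2 * pi * mean(mt$M[nrow(mt$M), -ncol(mt$M)])
  if (expected < 200)
    stop(sprintf(
      "configuration yields ~%.0f cones; at least 200 are required for 150-nearest-cone density estimation",
      expected))

  d_lat <- config$d0 / 1e6                       # cones per um^2
  s <- sqrt(2 / (sqrt(3) * d_lat))               # hexagonal lattice spacing
  rho_max <- sqrt(2 * max(mt$M[nrow(mt$M), ]) / d_lat) + 2 * s

  with_seed(config$seed, {
    rot <- stats::runif(1, 0, 2 * pi)
    off <- stats::runif(2, 0, s)
    ny <- ceiling(rho_max / (s * sqrt(3) / 2)) + 1
    rows <- seq(-ny, ny)
    pts <- do.call(rbind, lapply(rows, function(iy) {
      yy <- iy * s * sqrt(3) / 2 + off[2]
      xs <- seq(-ceiling(rho_max / s) - 1, ceiling(rho_max / s) + 1) * s +
        off[1] + (iy %% 2) * s / 2
      cbind(xs, yy)
    }))
    u <- pts[, 1] * cos(rot) - pts[, 2] * sin(rot)
    v <- pts[, 1] * sin(rot) + pts[, 2] * cos(rot)
    rho <- sqrt(u^2 + v^2)
    keep <- rho <= rho_max
    u <- u[keep]; v <- v[keep]; rho <- rho[keep]
    phi <- atan2(v, u)

    m <- d_lat * rho^2 / 2                       # lattice mass coordinate
    phi_deg <- (phi * 180 / pi) %% 360
    j <- floor(phi_deg) + 1                      # 1-degree angular bins
    wfrac <- phi_deg - (j - 1)
    Rmap <- rep(NA_real_, length(m))
    M_end <- mt$M[nrow(mt$M), ]
    for (bin in sort(unique(j))) {
      sel <- which(j == bin)
      lo <- stats::approx(mt$M[, bin], mt$r, xout = m[sel],
                          yleft = 0, yright = NA)$y
      hi <- stats::approx(mt$M[, bin + 1], mt$r, xout = m[sel],
                          yleft = 0, yright = NA)$y
      Rmap[sel] <- (1 - wfrac[sel]) * lo + wfrac[sel] * hi
    }
    ok <- !is.na(Rmap)
    x <- Rmap[ok] * cos(phi[ok])
    y <- Rmap[ok] * sin(phi[ok])
    # a minimal dither (2 nm) is always applied: exactly cocircular lattice
    # configurations are degenerate for Delaunay/Voronoi tessellations, and
    # no annotated mosaic is ever exact
    jit <- max(config$jitter_sd, 0.002)
    x <- x + stats::rnorm(length(x), 0, jit)
    y <- y + stats::rnorm(length(y), 0, jit)
    inside <- x^2 + y^2 <= R^2
    x <- x[inside]; y <- y[inside]
  })

  cone_mosaic(x, y, rmf = config$rmf, laterality = "synthetic",
              provenance = sprintf(
                "synthetic mosaic: seed=%d D0=%g field_radius=%g jitter_sd=%g rugosity=%g/%g",
                config$seed, config$d0, R, config$jitter_sd,
                config$rugosity_amplitude, config$rugosity_exponent))
}

#' Remove cones inside a central occlusion disk
#'
#' Simulates centrally obscured imagery (e.g., unresolved foveolar cones) by
#' deleting every cone strictly inside a disk and recording the occlusion
#' radius in the metadata. The input mosaic is not modified.
#'
#' @param mosaic A [cone_mosaic].
#' @param radius Occlusion radius (um), `>= 0`.
#' @param center Center of the occluded disk (um), default the origin.
#' @return A new [cone_mosaic] with `occlusion_radius` set.
#' @export
occlude_mosaic <- function(mosaic, radius, center = c(0, 0)) {
  stopifnot(inherits(mosaic, "cone_mosaic"))
  stop_if_not_number(radius, "radius", lower = 0)
  r2 <- (mosaic$x - center[1])^2 + (mosaic$y - center[2])^2
  keep <- r2 >= radius^2
  if (sum(keep) < 200)
    stop(sprintf("occlusion of radius %g um leaves %d cones; at least 200 are required",
                 radius, sum(keep)))
  out <- mosaic
  out$x <- mosaic$x[keep]
  out$y <- mosaic$y[keep]
  out$occlusion_radius <- radius
  out$provenance <- paste0(mosaic$provenance,
                           sprintf("; occluded r=%g um", radius))
  out
}
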