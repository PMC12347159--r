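# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# hexagonal lattice mosaic with spacing s (closed-form density 2/(sqrt(3) s^2))
hex_mosaic <- function(s = 2.54, half_rows = 40) {
  dy <- s * sqrt(3) / 2
  pts <- do.call(rbind, lapply(seq(-half_rows, half_rows), function(iy) {
    xs <- seq(-half_rows, half_rows) * s + (iy %% 2) * s / 2
    cbind(xs, iy * dy)
  }))
  cone_mosaic(pts[, 1], pts[, 2])
}

square_mosaic <- function(s = 2.5, half = 40) {
  g <- expand.grid(x = seq(-half, half) * s, y = seq(-half, half) * s)
  cone_mosaic(g$x, g$y)
}

hex_density <- function(s) 2 / (sqrt(3) * s^2) * 1e6   # cones/mm^2

# density_map built directly from an analytic field f(x, y) -> cones/mm^2
analytic_map <- function(f, spacing = 2, extent = 260, laterality = "OS") {
  gx <- seq(-extent, extent, by = spacing)
  gy <- gx
  vals <- outer(gx, gy, f)
  structure(list(x = gx, y = gy, values = vals,
                 valid = is.finite(vals), spacing = spacing,
                 laterality = laterality),
            class = "density_map")
}

# circular profile object from an analytic angular modulation
analytic_circular <- function(fun, eccentricity = 100, step = 1) {
  th <- seq(0, 360 - step, by = step)
  structure(list(eccentricity = eccentricity, theta = th,
                 density = fun(th), normalized = TRUE),
            class = "circular_profile")
}

# the standard anisotropic synthetic mosaic (group-average field, no jitter)
default_config <- function() generator_config(seed = 1, jitter_sd = 0)

default_mosaic <- function() fixture("default_mosaic", function() {
  generate_mosaic(default_config())
})

default_map <- function() fixture("default_map", function() {
  compute_density_map(default_mosaic(), grid_spacing = 2,
                      xlim = c(-260, 260), ylim = c(-260, 260))
})

default_metrics <- function() fixture("default_metrics", function() {
  compute_cdc(default_map())
})

# numeric integral of the target field over the disk of radius R (0.5 um grid)
field_integral <- function(config, R, dr = 0.5) {
  g <- seq(-R, R, by = dr)
  xx <- rep(g, times = length(g)); yy <- rep(g, each = length(g))
  inside <- xx^2 + yy^2 <= R^2
  sum(target_density(xx[inside], yy[inside], config)) / 1e6 * dr^2
}
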