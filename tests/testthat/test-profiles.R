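# analytic isotropic map shared by several blocks
iso_map <- function() fixture("iso_map", function() {
  p <- normative_params("radial")
  analytic_map(function(x, y) evaluate_model(p, sqrt(x^2 + y^2)),
               spacing = 2, extent = 260)
})

test_that("meridional profiles of an isotropic map are direction-free", {
  map <- iso_map()
  h <- meridional_profile(map, c(0, 0), "horizontal")
  v <- meridional_profile(map, c(0, 0), "vertical")
  common <- intersect(h$eccentricity, v$eccentricity)
  hv <- cbind(h$density[match(common, h$eccentricity)],
              v$density[match(common, v$eccentricity)])
  expect_lt(sqrt(mean((hv[, 1] / hv[, 2] - 1)^2)), 0.03)
})

test_that("anisotropic mosaic meridians cross half-density where published", {
  map <- default_map()
  tm <- default_metrics()
  h <- meridional_profile(map, tm$cdc_location, "horizontal")
  cross_h <- approx(h$density, h$eccentricity, xout = 0.5 * tm$d0)$y
  expect_equal(cross_h, 171, tolerance = 0.03)
  v <- meridional_profile(map, tm$cdc_location, "vertical")
  cross_v <- approx(v$density, v$eccentricity, xout = 0.5 * tm$d0)$y
  expect_equal(cross_v, 143.7, tolerance = 0.03)
})

test_that("quadrant sectors pool to the full meridian", {
  map <- default_map()
  tm <- default_metrics()
  n <- meridional_profile(map, tm$cdc_location, "nasal")
  t <- meridional_profile(map, tm$cdc_location, "temporal")
  h <- meridional_profile(map, tm$cdc_location, "horizontal")
  common <- Reduce(intersect, list(n$eccentricity, t$eccentricity,
                                   h$eccentricity))
  common <- common[common > 0]
  avg <- (n$density[match(common, n$eccentricity)] +
            t$density[match(common, t$eccentricity)]) / 2
  full <- h$density[match(common, h$eccentricity)]
  expect_lt(max(abs(avg / full - 1)), 0.01)
})

test_that("radial profile starts at D0 and matches published crossings", {
  map <- iso_map()
  p <- normative_params("radial")
  rp <- radial_profile(map, c(0, 0))
  expect_equal(rp$density[rp$eccentricity == 0], p$d0, tolerance = 1e-6)
  cross <- approx(rp$density, rp$eccentricity, xout = 0.5 * p$d0)$y
  expect_equal(cross, 151.3, tolerance = 0.01)
  # radial of an isotropic map equals its meridional profile
  h <- meridional_profile(map, c(0, 0), "horizontal")
  common <- intersect(rp$eccentricity, h$eccentricity)
  expect_lt(max(abs(rp$density[match(common, rp$eccentricity)] /
                      h$density[match(common, h$eccentricity)] - 1)), 0.02)
})

test_that("radial profile equals the angular mean of circular profiles", {
  map <- default_map()
  tm <- default_metrics()
  rp <- radial_profile(map, tm$cdc_location)
  for (E in c(40, 115, 200)) {
    cp <- circular_profile(map, tm$cdc_location, E)
    rv <- approx(rp$eccentricity, rp$density, xout = E)$y
    expect_lt(abs(mean(cp$density) / rv - 1), 0.01)
  }
})

test_that("normalization scales exactly, flags state, and round-trips", {
  p <- normative_params("radial")
  prof <- density_profile(0:100, evaluate_model(p, 0:100))
  np <- normalize_profile(prof, p$d0)
  expect_true(np$normalized)
  expect_equal(np$density[1], 1)
  expect_equal(np$density * p$d0, prof$density)
  expect_error(normalize_profile(np, p$d0), "already normalized")
  expect_error(normalize_profile(prof, 0), "d0")
})

test_that("circular profiles respect modulation and laterality convention", {
  p <- normative_params("radial")
  mod <- analytic_map(function(x, y) {
    E <- sqrt(x^2 + y^2); th <- atan2(y, x)
    evaluate_model(p, E) * (1 + 0.2 * cos(2 * th))
  }, spacing = 2, extent = 200)
  cp <- circular_profile(mod, c(0, 0), 100)
  expect_equal(cp$theta[which.max(cp$density)] %% 180, 0, tolerance = 2)
  troughs <- cp$theta[order(cp$density)[1:5]]
  expect_true(all(ang_diff(troughs, 90) < 10 | ang_diff(troughs, 270) < 10))
  # isotropic map -> flat circular profile
  cpi <- circular_profile(iso_map(), c(0, 0), 100)
  expect_lt(sd(cpi$density) / mean(cpi$density), 0.02)
  # a circle that exits the valid region is rejected
  expect_error(circular_profile(mod, c(0, 0), 500), "exits the valid")
  # OD maps mirror the x-axis: theta 0 (nasal) looks at map angle 180
  modOD <- mod; modOD$laterality <- "OD"
  cpOD <- circular_profile(modOD, c(0, 0), 100)
  expect_equal(cpOD$density[cpOD$theta == 0], cp$density[cp$theta == 180])
})

test_that("intercone distances match lattice spacing and scale linearly", {
  hex <- hex_mosaic(s = 2.54, half_rows = 30)
  icd <- intercone_distance_profile(hex, c(0, 0))
  inner <- icd$eccentricity < 40
  expect_true(all(abs(icd$density[inner] - 2.54) < 0.01))
  lam <- 2.2
  hex2 <- cone_mosaic(hex$x * lam, hex$y * lam)
  icd2 <- intercone_distance_profile(hex2, c(0, 0))
  inner2 <- icd2$eccentricity < 40 * lam
  expect_true(all(abs(icd2$density[inner2] - 2.54 * lam) < 0.01 * lam))
})

test_that("ICD relates to density as in hexagonal packing", {
  m <- default_mosaic()
  cfg <- default_config()
  icd <- intercone_distance_profile(m, c(0, 0), bin_width = 5)
  for (E in c(25, 100, 200)) {
    v <- approx(icd$eccentricity, icd$density, xout = E)$y
    pred <- sqrt(2 / (sqrt(3) * target_density(E, 0, cfg) / 1e6))
    pred_v <- sqrt(2 / (sqrt(3) * target_density(0, E, cfg) / 1e6))
    expect_lt(abs(v / mean(c(pred, pred_v)) - 1), 0.05)
  }
})

test_that("unit conversions are exact and invertible", {
  expect_equal(convert_units(1, "deg", "um", rmf = 291), 291)
  expect_equal(convert_units(175500, "cones_per_mm2", "cones_per_deg2",
                             rmf = 291), 14861.52, tolerance = 1e-6)
  for (u in c("um", "deg")) {
    x <- 123.4
    expect_equal(convert_units(convert_units(x, u,
      setdiff(c("um", "deg"), u), 302), setdiff(c("um", "deg"), u), u, 302), x)
  }
  x <- 2e5
  expect_equal(convert_units(convert_units(x, "cones_per_mm2",
    "cones_per_deg2", 275), "cones_per_deg2", "cones_per_mm2", 275), x)
  expect_error(convert_units(1, "um", "cones_per_mm2", 291), "unsupported")
})

test_that("slope metrics recover the model's steepest descent", {
  p <- normative_params("radial")
  sl <- profile_slope_metrics(p)
  # brute-force oracle: -877.9 (cones/mm^2)/um at 52.5 um for this triplet,
  # inside the published -870 +/- 184 at 51 +/- 8
  expect_equal(sl$max_slope, -877.88, tolerance = 0.001)
  expect_equal(sl$inflection, 52.46, tolerance = 0.001)
  # doubling D0 doubles the slope at the same eccentricity
  p2 <- sigmoid_params(2 * p$d0, p$a, p$b, p$c)
  sl2 <- profile_slope_metrics(p2)
  expect_equal(sl2$max_slope, 2 * sl$max_slope, tolerance = 1e-9)
  expect_equal(sl2$inflection, sl$inflection)
  # a profile input is fitted first
  prof <- density_profile(0:300, evaluate_model(p, 0:300))
  slp <- profile_slope_metrics(prof)
  expect_equal(slp$max_slope, sl$max_slope, tolerance = 1e-3)
})
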