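test_that("Voronoi cell areas match lattice closed forms", {
  hex <- hex_mosaic(s = 2.54)
  cells <- voronoi_cell_areas(hex)
  interior <- hex$x^2 + hex$y^2 < (30 * 2.54)^2
  expect_equal(unname(cells$areas[interior & !cells$unbounded][1]),
               sqrt(3) / 2 * 2.54^2, tolerance = 1e-6)
  expect_true(all(abs(cells$areas[interior] - sqrt(3) / 2 * 2.54^2) < 1e-6,
                  na.rm = TRUE))
  sq <- square_mosaic(s = 1, half = 20)
  cs <- voronoi_cell_areas(sq)
  int_sq <- abs(sq$x) < 15 & abs(sq$y) < 15
  expect_true(all(abs(cs$areas[int_sq] - 1) < 1e-9, na.rm = TRUE))
  # corner cells are unbounded
  corner <- which(sq$x == max(sq$x) & sq$y == max(sq$y))
  expect_true(cs$unbounded[corner])
  expect_error(voronoi_cell_areas(cone_mosaic(1:3, 1:3 * 2)), "collinear|4 cones")
})

test_that("k-nearest-cone density matches lattice closed forms", {
  hex <- hex_mosaic(s = 2.54)
  expect_equal(density_at_point(c(0.4, -0.3), hex), hex_density(2.54),
               tolerance = 0.005)
  sq <- square_mosaic(s = 2.5)
  expect_equal(density_at_point(c(0.7, 0.2), sq), 160000, tolerance = 0.005)
  # query outside the mosaic that drags in hull cones is invalid
  far <- density_at_point(c(max(hex$x) + 10, 0), hex)
  expect_true(is.na(far))
})

test_that("density scales as 1/lambda^2 under coordinate scaling", {
  hex <- hex_mosaic(s = 2.54, half_rows = 25)
  lam <- 1.7
  scaled <- cone_mosaic(hex$x * lam, hex$y * lam)
  d1 <- density_at_point(c(0.4, 0.2), hex)
  d2 <- density_at_point(c(0.4 * lam, 0.2 * lam), scaled)
  expect_equal(d2, d1 / lam^2, tolerance = 1e-6)
  a1 <- voronoi_cell_areas(hex)$areas
  a2 <- voronoi_cell_areas(scaled)$areas
  expect_equal(a2, a1 * lam^2, tolerance = 1e-6)
})

test_that("density maps of constant mosaics are flat and valid-masked", {
  const <- sigmoid_params(178979, 150, 1, 0)
  cfg <- generator_config(d0 = 178979, params_horizontal = const,
                          params_vertical = const, field_radius = 120,
                          jitter_sd = 0, seed = 9)
  m <- generate_mosaic(cfg)
  map <- compute_density_map(m, grid_spacing = 4,
                             xlim = c(-80, 80), ylim = c(-80, 80))
  v <- map$values[map$valid]
  expect_gt(length(v), 100)
  expect_lt(sd(v) / mean(v), 0.03)
})

test_that("map maximum reflects the configured central density", {
  map <- default_map()
  cfg <- default_config()
  expect_lt(abs(max(map$values[map$valid]) / cfg$d0 - 1), 0.05)
})

test_that("CDC sits at the center of a symmetric map and D0 <= PCD", {
  tm <- default_metrics()
  expect_lt(sqrt(sum(tm$cdc_location^2)), default_map()$spacing)
  expect_lte(tm$d0, tm$pcd)
  expect_false(tm$border_warning)
  expect_gt(tm$isoa_top20, 0)
})

test_that("CDC is translation-equivariant", {
  m <- default_mosaic()
  shift <- c(37, -12)
  m2 <- cone_mosaic(m$x + shift[1], m$y + shift[2])
  map1 <- compute_density_map(m, grid_spacing = 4,
                              xlim = c(-100, 100), ylim = c(-100, 100))
  map2 <- compute_density_map(m2, grid_spacing = 4,
                              xlim = c(-100, 100) + shift[1],
                              ylim = c(-100, 100) + shift[2])
  c1 <- compute_cdc(map1)$cdc_location
  c2 <- compute_cdc(map2)$cdc_location
  expect_equal(c2, c1 + shift, tolerance = 1e-9)
})

test_that("PCD and D0 are rotation-invariant and the CDC rotates", {
  m <- generate_mosaic(generator_config(seed = 6, field_radius = 150,
                                        jitter_sd = 0.25))
  ang <- deg2rad(30)
  m2 <- cone_mosaic(m$x * cos(ang) - m$y * sin(ang),
                    m$x * sin(ang) + m$y * cos(ang))
  lims <- c(-100, 100)
  map1 <- compute_density_map(m, grid_spacing = 3, xlim = lims, ylim = lims)
  map2 <- compute_density_map(m2, grid_spacing = 3, xlim = lims, ylim = lims)
  t1 <- compute_cdc(map1); t2 <- compute_cdc(map2)
  expect_lt(abs(t2$pcd / t1$pcd - 1), 0.005)
  expect_lt(abs(t2$d0 / t1$d0 - 1), 0.005)
  rot <- c(t1$cdc_location[1] * cos(ang) - t1$cdc_location[2] * sin(ang),
           t1$cdc_location[1] * sin(ang) + t1$cdc_location[2] * cos(ang))
  expect_lt(sqrt(sum((t2$cdc_location - rot)^2)), 2 * map1$spacing)
})

test_that("iso-density contour metrics capture shape", {
  p <- normative_params("radial")
  iso <- analytic_map(function(x, y)
    evaluate_model(p, sqrt(x^2 + y^2)), spacing = 2, extent = 250)
  met <- iso_density_contour_metrics(iso, 0.6 * p$d0, c(0, 0))
  expect_equal(met$aspect_ratio, 1, tolerance = 0.05)
  r60 <- fraction_crossing(p, 0.6)
  expect_equal(met$area, pi * r60^2, tolerance = 0.02)
  # x stretched by 1.3 -> aspect ratio 1.3
  stretch <- analytic_map(function(x, y)
    evaluate_model(p, sqrt((x / 1.3)^2 + y^2)), spacing = 2, extent = 250)
  met2 <- iso_density_contour_metrics(stretch, 0.6 * p$d0, c(0, 0))
  expect_equal(met2$aspect_ratio, 1.3, tolerance = 0.05)
  expect_error(iso_density_contour_metrics(iso, 2 * p$d0, c(0, 0)),
               "outside the valid map range")
})

test_that("cone counts in regions are additive and match area x density", {
  hex <- hex_mosaic(s = 2.54, half_rows = 35)
  s <- 2.54
  cnt <- cones_in_region(hex, c(0, 0), 0, 10 * s)
  expect_lt(abs(cnt / (pi * (10 * s)^2 * hex_density(s) / 1e6) - 1), 0.05)
  total <- cones_in_region(hex, c(0, 0), 0, Inf)
  expect_equal(total, n_cones(hex))
  r1 <- cones_in_region(hex, c(0, 0), 0, 20)
  r2 <- cones_in_region(hex, c(0, 0), 20, 45)
  r3 <- cones_in_region(hex, c(0, 0), 45, 70)
  expect_equal(r1 + r2 + r3, cones_in_region(hex, c(0, 0), 0, 70))
  expect_error(cones_in_region(hex, c(0, 0), 10, 10), "r_inner < r_outer")
})
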