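test_that("target density obeys its defining field", {
  cfg <- default_config()
  # origin is exactly D0, regardless of rugosity
  expect_equal(target_density(0, 0, cfg), cfg$d0)
  cfg_rug <- generator_config(rugosity_amplitude = 0.3, seed = 1)
  expect_equal(target_density(0, 0, cfg_rug), cfg_rug$d0)
  # on-axis the field reduces to the meridional triplets: 50% crossings
  expect_equal(target_density(171.085, 0, cfg), 0.5 * cfg$d0,
               tolerance = 1e-4)
  expect_equal(target_density(0, 143.748, cfg), 0.5 * cfg$d0,
               tolerance = 1e-4)
  # angular mean of the rugosity modulation is one
  th <- seq(0, 2 * pi, length.out = 7200)[-7200]
  E <- 100
  iso <- generator_config(params_horizontal = normative_params("radial"),
                          params_vertical = normative_params("radial"),
                          seed = 1)
  base <- mean(target_density(E * cos(th), E * sin(th), iso))
  mod <- generator_config(params_horizontal = normative_params("radial"),
                          params_vertical = normative_params("radial"),
                          rugosity_amplitude = 0.3, seed = 1)
  modm <- mean(target_density(E * cos(th), E * sin(th), mod))
  expect_equal(modm / base, 1, tolerance = 1e-4)
})

test_that("generated mosaics are deterministic and bounded by the field radius", {
  cfg <- generator_config(seed = 3, field_radius = 150, jitter_sd = 0.25)
  m1 <- generate_mosaic(cfg)
  m2 <- generate_mosaic(cfg)
  expect_identical(m1$x, m2$x)
  expect_identical(m1$y, m2$y)
  expect_true(all(m1$x^2 + m1$y^2 <= 150^2))
  m3 <- generate_mosaic(generator_config(seed = 4, field_radius = 150))
  expect_false(identical(m1$x, m3$x))
})

test_that("constant-density mosaics match the hexagonal closed form", {
  # a -> 150, b = 1, c = 0 makes the sigmoid identically one
  const <- sigmoid_params(178979, 150, 1, 0)
  cfg <- generator_config(d0 = 178979, params_horizontal = const,
                          params_vertical = const, field_radius = 150,
                          jitter_sd = 0, seed = 7)
  m <- generate_mosaic(cfg)
  cells <- voronoi_cell_areas(m)
  set.seed(1)
  th <- runif(30, 0, 2 * pi); r <- sqrt(runif(30)) * 110
  meas <- density_at_point(cbind(r * cos(th), r * sin(th)), m, cells = cells)
  expect_true(all(abs(meas / 178979 - 1) < 0.05))
})

test_that("total cone count matches the integral of the target field", {
  cfg <- default_config()
  m <- default_mosaic()
  expected <- field_integral(cfg, cfg$field_radius)
  expect_lt(abs(n_cones(m) / expected - 1), 0.05)
})

test_that("measured density tracks the prescribed anisotropic field", {
  cfg <- default_config()
  m <- default_mosaic()
  cells <- voronoi_cell_areas(m)
  for (E in c(10, 60, 120, 180, 240)) {
    th <- seq(0, 2 * pi, length.out = 13)[-13]
    meas <- density_at_point(cbind(E * cos(th), E * sin(th)), m,
                             cells = cells)
    tgt <- target_density(E * cos(th), E * sin(th), cfg)
    expect_true(all(abs(meas / tgt - 1) < 0.05),
                label = sprintf("density within 5%% of target at E = %g", E))
  }
})

test_that("interior cones are quasi-hexagonal (5-7 Voronoi neighbors)", {
  m <- generate_mosaic(generator_config(seed = 5, field_radius = 150,
                                        jitter_sd = 0.25))
  dd <- deldir::deldir(m$x, m$y)
  cells <- voronoi_cell_areas(m)
  nbr <- table(factor(c(dd$dirsgs$ind1, dd$dirsgs$ind2),
                      levels = seq_len(n_cones(m))))
  interior <- !cells$unbounded & (m$x^2 + m$y^2) < 130^2
  counts <- as.integer(nbr)[interior]
  expect_gt(mean(counts >= 5 & counts <= 7), 0.995)
  expect_equal(median(counts), 6)
})

test_that("isotropic configurations yield isotropic measured profiles", {
  rad <- normative_params("radial")
  rms <- vapply(1:6, function(s) {
    cfg <- generator_config(params_horizontal = rad, params_vertical = rad,
                            field_radius = 200, jitter_sd = 0.25, seed = s)
    m <- generate_mosaic(cfg)
    cells <- voronoi_cell_areas(m)
    E <- seq(10, 160, by = 15)
    h <- density_at_point(cbind(c(E, -E), rep(0, 2 * length(E))), m,
                          cells = cells)
    v <- density_at_point(cbind(rep(0, 2 * length(E)), c(E, -E)), m,
                          cells = cells)
    sqrt(mean((h / v - 1)^2))
  }, numeric(1))
  expect_lt(mean(rms), 0.03)
})

test_that("undersized configurations are rejected", {
  tiny <- sigmoid_params(5000, 150, 1, 0)
  expect_error(generate_mosaic(
    generator_config(d0 = 100, params_horizontal = tiny,
                     params_vertical = tiny, field_radius = 30)),
    "at least 200")
})

test_that("occlusion removes exactly the central cones", {
  m <- generate_mosaic(generator_config(seed = 2, field_radius = 150))
  occ <- occlude_mosaic(m, 50)
  expect_equal(occ$occlusion_radius, 50)
  expect_true(all(occ$x^2 + occ$y^2 >= 50^2))
  expect_equal(n_cones(occ), sum(m$x^2 + m$y^2 >= 50^2))
  # the original is untouched and radius 0 removes nothing
  expect_equal(n_cones(m), length(m$x))
  m0 <- occlude_mosaic(m, 0)
  expect_equal(m0$x, m$x)
  expect_equal(m0$occlusion_radius, 0)
  # count drop matches the field integral over the occluded disk
  cfg <- default_config()
  big <- default_mosaic()
  occ75 <- occlude_mosaic(big, 75)
  removed <- n_cones(big) - n_cones(occ75)
  expect_lt(abs(removed / field_integral(cfg, 75) - 1), 0.05)
  # occluding (almost) everything is rejected
  expect_error(occlude_mosaic(m, 149), "at least 200")
})
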