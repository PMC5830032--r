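test_that("window area tallies target cells times cell area", {
  g <- pa_grid(matrix(0, 8, 8))
  all_target <- matrix(TRUE, 8, 8)
  # no partnering: one cell, 1 km^2
  a0 <- compute_area(all_target, build_kernel(0), template = g)
  expect_true(all(a0$values == 1))
  # interior cells at r = 3 see the full 29-cell window
  a3 <- compute_area(all_target, build_kernel(3), template = g)
  expect_identical(a3$values[4, 4], 29)
  expect_identical(a3$values[5, 5], 29)
  # cell size rescales area
  g2 <- pa_grid(matrix(0, 8, 8), cell_km = 2)
  a2 <- compute_area(matrix(TRUE, 8, 8), build_kernel(0, 2), template = g2)
  expect_true(all(a2$values == 4))
  # random masks match the brute-force count oracle
  set.seed(14)
  mask <- matrix(runif(64) < 0.5, 8, 8)
  k2 <- build_kernel(2)
  expect_identical(compute_area(mask, k2, template = g)$values,
                   brute_focal(matrix(1, 8, 8), k2, mask, "count"))
})

test_that("latitudinal range spans the window rows in degrees", {
  # rows at 40.00, 40.01, ..., 40.09: radius 3 reaches rows +-3
  lat <- seq(40.00, 40.09, by = 0.01)
  g <- pa_grid(matrix(0, 10, 10), row_latitudes = lat)
  L <- compute_lat_range(latitude_grid(g), matrix(TRUE, 10, 10),
                         build_kernel(3))
  expect_equal(L$values[5, 5], 0.06, tolerance = 1e-12)
  # radius 0 and constant-latitude landscapes give zero range
  L0 <- compute_lat_range(latitude_grid(g), matrix(TRUE, 10, 10),
                          build_kernel(0))
  expect_true(all(L0$values == 0))
  gc <- pa_grid(matrix(0, 4, 8), row_latitudes = rep(12, 4))
  Lc <- compute_lat_range(latitude_grid(gc), matrix(TRUE, 4, 8),
                          build_kernel(2))
  expect_true(all(Lc$values == 0))
})

test_that("elevational range matches the brute-force max-min oracle", {
  set.seed(15)
  e <- matrix(runif(100, 0, 2000), 10, 10)
  mask <- matrix(runif(100) < 0.7, 10, 10)
  k <- build_kernel(2)
  E <- compute_elev_range(pa_grid(e), mask, k)
  expect_identical(E$values,
                   brute_focal(e, k, mask, "max") - brute_focal(e, k, mask, "min"))
  # flat terrain and identity windows give zero
  expect_true(all(compute_elev_range(pa_grid(matrix(7, 5, 5)),
                                     matrix(TRUE, 5, 5), k)$values == 0))
  expect_true(all(compute_elev_range(pa_grid(e), mask,
                                     build_kernel(0))$values == 0,
                  na.rm = TRUE))
})

test_that("relief-weighted hydrologic area sums network relief above the window minimum", {
  # hand-built 5-cell window: min over target cells is 90; network cells sit
  # at 100, 150, 200 -> H = 10 + 60 + 110 = 180
  e <- matrix(0, 3, 3)
  e[2, 2] <- 90; e[1, 2] <- 100; e[3, 2] <- 150; e[2, 1] <- 200; e[2, 3] <- 95
  target <- matrix(FALSE, 3, 3)
  target[2, 2] <- target[1, 2] <- target[3, 2] <- target[2, 1] <- target[2, 3] <- TRUE
  hydro <- matrix(FALSE, 3, 3)
  hydro[1, 2] <- hydro[3, 2] <- hydro[2, 1] <- TRUE
  H <- compute_relief_hydro(pa_grid(e), hydro, target, build_kernel(1))
  expect_identical(H$values[2, 2], 180)
  # flat terrain: zero relief regardless of network density
  Hf <- compute_relief_hydro(pa_grid(matrix(5, 6, 6)), matrix(TRUE, 6, 6),
                             matrix(TRUE, 6, 6), build_kernel(2))
  expect_true(all(Hf$values == 0))
  # no network cells in the window: zero, not nodata
  Hn <- compute_relief_hydro(pa_grid(e), matrix(FALSE, 3, 3), target,
                             build_kernel(1))
  expect_identical(Hn$values[2, 2], 0)
  # randomized agreement with the direct window evaluation
  set.seed(16)
  eb <- matrix(runif(144, 0, 500), 12, 12)
  hb <- matrix(runif(144) < 0.3, 12, 12)
  tb <- matrix(runif(144) < 0.6, 12, 12)
  k2 <- build_kernel(2)
  expect_equal(compute_relief_hydro(pa_grid(eb), hb, tb, k2)$values,
               brute_relief_hydro(eb, hb & tb, tb, k2), tolerance = 1e-12)
})

test_that("climate-area velocity divides the mean rate by the spatial sd plus floor", {
  # zero-variance baseline: denominator collapses to the 0.1 floor
  now <- pa_grid(matrix(10, 6, 6))
  fut <- pa_grid(matrix(10 + 0.05 * 95, 6, 6))
  V <- compute_climate_area_velocity(now, fut, 95, matrix(TRUE, 6, 6),
                                     build_kernel(2))
  expect_equal(V$values[3, 3], 0.5, tolerance = 1e-12)
  # baseline {10..14} in the window, uniform 0.04 /yr rate
  now5 <- pa_grid(matrix(10:14, 1, 5, byrow = TRUE))
  fut5 <- pa_grid(matrix(10:14 + 0.04 * 50, 1, 5, byrow = TRUE))
  V5 <- compute_climate_area_velocity(now5, fut5, 50, matrix(TRUE, 1, 5),
                                      build_kernel(2))
  expect_equal(V5$values[1, 3], 0.04 / (sqrt(2) + 0.1), tolerance = 1e-9)
  # no change: zero velocity
  V0 <- compute_climate_area_velocity(now, now, 95, matrix(TRUE, 6, 6),
                                      build_kernel(2))
  expect_true(all(V0$values == 0))
  expect_error(compute_climate_area_velocity(now, fut, 0,
                                             matrix(TRUE, 6, 6),
                                             build_kernel(1)), "positive")
  # sign of change is discarded by the outer absolute value
  cool <- pa_grid(matrix(10 - 0.05 * 95, 6, 6))
  Vc <- compute_climate_area_velocity(now, cool, 95, matrix(TRUE, 6, 6),
                                      build_kernel(2))
  expect_equal(Vc$values, V$values)
})

test_that("velocity scales inversely with baseline spatial sd when the floor is off", {
  set.seed(17)
  base <- matrix(rnorm(81, 0, 2), 9, 9)
  now1 <- pa_grid(base)
  now2 <- pa_grid(base * 2)  # doubles every window sd
  fut1 <- pa_grid(base + 1)
  fut2 <- pa_grid(base * 2 + 1)
  k <- build_kernel(2)
  v1 <- compute_climate_area_velocity(now1, fut1, 10, matrix(TRUE, 9, 9), k,
                                      floor_constant = 0)
  v2 <- compute_climate_area_velocity(now2, fut2, 10, matrix(TRUE, 9, 9), k,
                                      floor_constant = 0)
  expect_equal(v2$values, v1$values / 2, tolerance = 1e-12)
})

test_that("climate-space retention falls from one to zero as the shift grows", {
  r0 <- simulate_climate_space_retention(0, 1, n = 10000, seed = 1)
  expect_gte(r0$retention, 0.98)
  rfar <- simulate_climate_space_retention(10, 1, n = 10000, seed = 1)
  expect_lte(rfar$retention, 0.001)
  expect_identical(rfar$area_factor,
                   if (rfar$retention > 0) 1 / rfar$retention else Inf)
  # area factors: reciprocal retention, +1 adjustment for the current space
  r1 <- simulate_climate_space_retention(1, 1, n = 5000, seed = 2)
  expect_equal(r1$area_factor_adjusted, r1$area_factor + 1)
  expect_error(simulate_climate_space_retention(0, 0), "sd")
  expect_error(simulate_climate_space_retention(0, 1, n = 1), "n")
})
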