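test_that("the pixel null model is the exact no-partnering limit", {
  ls <- test_landscape(n = 20, seed = 4)
  iset <- run_scenario(ls, "pixel_null")
  pa <- ls$pa_ids$values > 0
  expect_true(all(iset$area_A$values[pa] == 1))
  expect_true(all(iset$lat_range_L$values[pa] == 0))
  expect_true(all(iset$elev_range_E$values[pa] == 0))
  expect_true(all(iset$relief_hydro_H$values[pa] == 0))
  rate <- abs(ls$temp_future$values - ls$temp_now$values) / ls$years_elapsed
  expect_equal(iset$velocity_T$values[pa], rate[pa] / 0.1, tolerance = 1e-12)
  # non-PA cells are outside the default focal domain
  expect_true(all(is.na(iset$area_A$values[!pa])))
})

test_that("the PA null model equals the whole-PA reduction on a rectangular PA", {
  # one hand-placed rectangular PA
  p <- landscape_params(n_rows = 16, n_cols = 16, relief_m = 600,
                        pa_fraction = 0, n_pas = 0, seed = 6)
  ls <- synthetic_landscape(p)
  ids <- matrix(0, 16, 16)
  ids[4:9, 5:12] <- 1
  ls$pa_ids <- pa_grid(ids, cell_km = 1,
                       row_latitudes = ls$elevation$row_latitudes,
                       units = "id")
  iset <- run_scenario(ls, "pa_null")
  cells <- which(ids == 1)
  e <- ls$elevation$values[cells]
  latm <- matrix(ls$elevation$row_latitudes, 16, 16)
  hydro <- ls$hydro$values[cells] > 0
  expect_true(all(iset$area_A$values[cells] == length(cells)))
  expect_equal(unique(iset$elev_range_E$values[cells]), max(e) - min(e))
  expect_equal(unique(iset$lat_range_L$values[cells]),
               max(latm[cells]) - min(latm[cells]))
  expect_equal(unique(iset$relief_hydro_H$values[cells]),
               sum(ls$elevation$values[cells][hydro] - min(e)))
  rate <- (ls$temp_future$values - ls$temp_now$values) / ls$years_elapsed
  sd_pop <- sqrt(mean((ls$temp_now$values[cells] -
                         mean(ls$temp_now$values[cells]))^2))
  expect_equal(unique(iset$velocity_T$values[cells]),
               abs(mean(rate[cells])) / (sd_pop + 0.1), tolerance = 1e-12)
  expect_true(all(is.na(iset$area_A$values[ids == 0])))
})

test_that("scenario modes dominate cell-wise: PA & non-PA >= PA-only >= pixel null", {
  ls <- test_landscape(n = 24, seed = 8)
  r <- 3
  i_np <- run_scenario(ls, "pa_nonpa_partnership", radius_km = r)
  i_pa <- run_scenario(ls, "pa_partnership", radius_km = r)
  i_px <- run_scenario(ls, "pixel_null")
  for (nm in c("area_A", "lat_range_L", "elev_range_E", "relief_hydro_H")) {
    a <- i_np[[nm]]$values; b <- i_pa[[nm]]$values; c0 <- i_px[[nm]]$values
    ok <- !is.na(a) & !is.na(b) & !is.na(c0)
    expect_true(all(a[ok] >= b[ok]), label = paste(nm, "np >= pa"))
    expect_true(all(b[ok] >= c0[ok]), label = paste(nm, "pa >= pixel"))
  }
  expect_error(run_scenario(ls, "pa_partnership"), "radius")
  # a PA-free landscape has no focal domain for PA modes
  ls0 <- synthetic_landscape(landscape_params(n_rows = 8, n_cols = 8,
                                              pa_fraction = 0, n_pas = 0))
  expect_error(run_scenario(ls0, "pa_partnership", radius_km = 3),
               "empty domain")
})

test_that("comparison factors carry the signed increase/decrease convention", {
  expect_identical(comparison_factor(2, 1), 2)
  expect_identical(comparison_factor(1, 1), 1)
  expect_equal(comparison_factor(0.4, 0.6), -1.5, tolerance = 1e-12)
  expect_true(all(abs(comparison_factor(runif(20, 0.1, 5),
                                        runif(20, 0.1, 5))) >= 1))
  expect_error(comparison_factor(0, 1), "positive")
  expect_error(comparison_factor(1, -2), "positive")
})

test_that("scenario comparisons show partnership gains and velocity declines", {
  ls <- test_landscape(n = 32, seed = 10)
  cmp <- compare_scenarios(ls, radius_km = 9)
  expect_identical(nrow(cmp), 5L * 6L)
  gains <- dplyr::filter(cmp, numerator == "pa_nonpa_partnership",
                         denominator == "pixel_null",
                         indicator == "area_A")
  expect_gt(gains$factor, 1)
  vel <- dplyr::filter(cmp, numerator == "pa_nonpa_partnership",
                       denominator == "pixel_null",
                       indicator %in% c("velocity_T", "velocity_P"))
  expect_true(all(vel$factor < 0))  # partnerships decrease velocity
})

test_that("partner composition reports window PA percentages and majority shares", {
  # all-PA landscape: 100% everywhere, both summaries 100
  all_pa <- pa_grid(matrix(1, 10, 10))
  pc <- partner_composition(all_pa, build_kernel(2))
  expect_true(all(pc$percent_pa$values == 100))
  expect_equal(pc$summary$mean_pct[pc$summary$focal_class == "pa"], 100)
  expect_equal(pc$summary$pct_gt50[pc$summary$focal_class == "pa"], 100)
  # PA-free landscape: 0% for non-PA focal cells
  no_pa <- pa_grid(matrix(0, 10, 10))
  pc0 <- partner_composition(no_pa, build_kernel(2))
  expect_true(all(pc0$percent_pa$values == 0))
  expect_equal(pc0$summary$mean_pct[pc0$summary$focal_class == "non_pa"], 0)
  # random mask equals brute-force window counts
  set.seed(19)
  mask <- matrix(rbinom(144, 1, 0.3), 12, 12)
  k <- build_kernel(2)
  pcr <- partner_composition(pa_grid(mask), k)
  n_land <- brute_focal(matrix(1, 12, 12), k, matrix(TRUE, 12, 12), "count")
  n_pa <- brute_focal(matrix(1, 12, 12), k, mask == 1, "count")
  n_pa[is.na(n_pa)] <- 0
  expect_equal(pcr$percent_pa$values, 100 * n_pa / n_land, tolerance = 1e-12)
  expect_true(all(pcr$percent_pa$values >= 0 & pcr$percent_pa$values <= 100))
})

test_that("interior mean composition recovers the global PA fraction on a periodic mosaic", {
  # 4-periodic mask, focal block spanning whole periods, untruncated windows
  tile <- matrix(0, 4, 4); tile[1, 1] <- 1; tile[2, 3] <- 1  # 1/8 cover
  mask <- tile[rep(1:4, 6), rep(1:4, 6)]  # 24 x 24
  k <- build_kernel(3)
  pc <- partner_composition(pa_grid(mask), k)
  interior <- matrix(FALSE, 24, 24)
  interior[5:20, 5:20] <- TRUE  # 16 = 4 periods, windows fully in bounds
  expect_equal(mean(pc$percent_pa$values[interior]), 100 / 8,
               tolerance = 1e-9)
})

test_that("partnership percentiles interpolate the sorted size table", {
  single <- partnership_percentiles(tibble::tibble(area_km2 = 7))
  expect_equal(single$area_km2, rep(7, 3))
  expect_equal(partnership_percentiles(1:100)$area_km2[2], 50.5)
  set.seed(20)
  areas <- runif(37, 10, 1e6)
  got <- partnership_percentiles(areas)$area_km2
  expect_equal(got, unname(quantile(sort(areas), c(0.05, 0.5, 0.95))))
  expect_error(partnership_percentiles(numeric(0)), "non-empty")
  expect_error(partnership_percentiles(c(3, -1)), "positive")
})

test_that("equivalent circular radii invert the window-area relation", {
  expect_identical(area_to_radius(3.3e4, rounded = TRUE), 102)
  expect_identical(area_to_radius(185502, rounded = TRUE), 243)
  expect_equal(area_to_radius(pi), 1, tolerance = 1e-12)
  r <- c(0.5, 1, 3, 81, 729)
  expect_equal(area_to_radius(pi * r^2), r, tolerance = 1e-9)
  expect_error(area_to_radius(-3), "positive")
})

test_that("indicator sets tidy and glance into scenario summary tables", {
  ls <- test_landscape(n = 20, seed = 12)
  iset <- run_scenario(ls, "pa_partnership", radius_km = 3)
  td <- tidy(iset)
  expect_identical(nrow(td), 6L)
  expect_true(all(c("indicator", "mean", "sd", "n_cells") %in% names(td)))
  expect_true(all(td$n_cells == sum(ls$pa_ids$values > 0)))
  gl <- glance(iset)
  expect_identical(nrow(gl), 1L)
  expect_equal(gl$area_A, td$mean[td$indicator == "area_A"])
})
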