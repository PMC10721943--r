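small_cfg <- function(...) {
  landscape_config(width_m = 40, height_m = 40, relief_amplitude_m = 10,
                   roughness = 0.3, formation_fraction = 0.3, seed = 11, ...)
}

test_that("DEM generation is deterministic, finite, amplitude-controlled", {
  cfg <- small_cfg()
  d1 <- generate_dem(cfg)
  d2 <- generate_dem(cfg)
  expect_identical(d1$values, d2$values)
  expect_true(all(is.finite(d1$values)))
  expect_equal(diff(range(d1$values)), 10)
  flat <- generate_dem(landscape_config(width_m = 20, height_m = 20,
                                        relief_amplitude_m = 0, seed = 1))
  expect_true(all(flat$values == 0))
})

test_that("larger relief amplitude gives strictly larger elevation variance", {
  vars <- sapply(c(1, 10), function(amp) {
    mean(sapply(1:50, function(s) {
      cfg <- landscape_config(width_m = 30, height_m = 30,
                              relief_amplitude_m = amp, roughness = 0.3,
                              seed = s)
      var(as.vector(generate_dem(cfg)$values))
    }))
  })
  expect_gt(vars[2], vars[1])
})

test_that("smoother terrain (lower roughness) has higher lag-1 autocorrelation", {
  acf1 <- function(rough) {
    cfg <- landscape_config(width_m = 60, height_m = 60,
                            relief_amplitude_m = 10, roughness = rough,
                            seed = 5)
    v <- generate_dem(cfg)$values
    cor(as.vector(v[, -1]), as.vector(v[, -ncol(v)]))
  }
  expect_gt(acf1(0.1), acf1(2))
})

test_that("geology mask fraction tracks the target and matches its polygons", {
  cfg <- landscape_config(width_m = 200, height_m = 200,
                          formation_fraction = 0.3, seed = 21)
  g <- generate_geology(cfg)
  frac <- mean(g$mask$values)
  expect_gte(frac, 0.24)
  expect_lte(frac, 0.36)
  # vector/raster consistency on a subsample of cell centres (ray-casting
  # oracle, even-odd per polygon combined by union)
  cc <- cell_centers(g$mask)
  idx <- withr::with_seed(1, sample.int(nrow(cc), 300))
  for (i in idx) {
    ins <- any(vapply(g$polygons, oracle_point_in_polygon,
                      TRUE, px = cc$x[i], py = cc$y[i]))
    expect_equal(cc$value[i] > 0, ins)
  }
})

test_that("empty polygon set yields an all-zero mask via points_in_polygons", {
  expect_equal(points_in_polygons(list(), c(1, 2), c(1, 2)),
               c(FALSE, FALSE))
})

test_that("precipitation gradient spans low..high from north to south", {
  cfg <- landscape_config(width_m = 4000, height_m = 4000, cell_size_m = 10,
                          seed = 1)
  p <- generate_precipitation(cfg, low = 220, high = 320)
  expect_equal(min(p$values), 220)
  expect_equal(max(p$values), 320)
  row_means <- rowMeans(p$values)      # row 1 = north
  expect_true(all(diff(row_means) > 0))
  expect_error(generate_precipitation(cfg, low = 320, high = 320),
               "strictly less")
  near_const <- generate_precipitation(cfg, low = 250, high = 250 + 1e-9)
  expect_lt(diff(range(near_const$values)), 1e-8)
})

test_that("spectral bands elevate the soil colour index on the formation", {
  mask <- grid_raster(matrix(rep(c(1, 0), each = 200), 20, 20), cellsize = 1)
  noiseless <- generate_spectral_bands(mask, on_red = 0.3, on_green = 0.1,
                                       off_red = 0.2, off_green = 0.2,
                                       noise_sd = 0, seed = 1)
  idx <- soil_color_index(noiseless$red, noiseless$green)
  expect_equal(unique(idx$values[mask$values == 1]), 0.5)
  expect_equal(unique(idx$values[mask$values == 0]), 0)
  cfg <- landscape_config(width_m = 200, height_m = 200,
                          formation_fraction = 0.3, seed = 8)
  g <- generate_geology(cfg)
  b1 <- generate_spectral_bands(g$mask, noise_sd = 0.02, seed = 4)
  b2 <- generate_spectral_bands(g$mask, noise_sd = 0.02, seed = 4)
  expect_identical(b1$red$values, b2$red$values)
  noisy_idx <- soil_color_index(b1$red, b1$green)
  expect_gt(mean(noisy_idx$values[g$mask$values == 1]),
            mean(noisy_idx$values[g$mask$values == 0]))
})

test_that("logistic truth obeys its closed-form limits and monotonicity", {
  z <- matrix(seq(-2, 2, length.out = 25), 5, 5)
  layers <- list(a = grid_raster(z), b = grid_raster(z * 0 + 1))
  flat <- define_true_suitability(layers, c(a = 0), intercept = 0)
  expect_true(all(flat$suitability$values == 0.5))
  tail <- define_true_suitability(layers, c(a = 0), intercept = -10)
  expect_true(all(tail$suitability$values < 1e-4))
  mono <- define_true_suitability(layers, c(a = 1), intercept = 0)
  o <- order(as.vector(z))
  expect_true(all(diff(as.vector(mono$suitability$values)[o]) > 0))
  expect_error(define_true_suitability(layers, c(missing_cov = 1)),
               "no covariate layer")
})

test_that("virtual species samples follow the truth surface", {
  z <- matrix(0, 50, 50)
  layers <- list(a = grid_raster(z))
  flat_truth <- define_true_suitability(layers, c(a = 0), intercept = 0)
  empty <- sample_virtual_species(flat_truth, 0, 0, seed = 1)
  expect_equal(nrow(empty$points), 0)
  expect_equal(length(empty$polygons), 0)
  # uniform truth: quadrat-count chi-square GOF should not reject
  s <- sample_virtual_species(flat_truth, 2000, 0, seed = 9)
  qx <- cut(s$points$x, breaks = seq(0, 50, by = 10))
  qy <- cut(s$points$y, breaks = seq(0, 50, by = 10))
  counts <- as.vector(table(qx, qy))
  gof <- chisq.test(counts)
  expect_gt(gof$p.value, 0.01)
  # truth supported on one patch only: every sample lands inside it
  patchy <- define_true_suitability(list(a = grid_raster(matrix(0, 50, 50))),
                                    c(a = 0))
  support <- matrix(0, 50, 50)
  support[11:20, 11:20] <- 1
  patchy$suitability$values <- support
  sp <- sample_virtual_species(patchy, 300, 0, seed = 2)
  ins <- raster_value_at(patchy$suitability, sp$points$x, sp$points$y)
  expect_true(all(ins == 1))
})

test_that("survey cells respect detection rules and suitability ordering", {
  z <- matrix(seq(-3, 3, length.out = 10000), 100, 100)
  truth <- define_true_suitability(list(a = grid_raster(z)), c(a = 2))
  none <- generate_survey_cells(truth$suitability, n_cells = 50,
                                cell_size_m = 10,
                                detection_rule = function(p) 0 * p, seed = 1)
  expect_true(all(none$detected == 0))
  all_det <- generate_survey_cells(truth$suitability, n_cells = 50,
                                   cell_size_m = 10,
                                   detection_rule = function(p) 0 * p + 1,
                                   seed = 1)
  expect_true(all(all_det$detected == 1))
  cells <- generate_survey_cells(truth$suitability, n_cells = 80,
                                 cell_size_m = 10, seed = 3)
  expect_gt(mean(cells$truth_mean[cells$detected == 1]),
            mean(cells$truth_mean[cells$detected == 0]))
  expect_error(generate_survey_cells(truth$suitability, n_cells = 5,
                                     cell_size_m = 7.5),
               "integer multiple")
})
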