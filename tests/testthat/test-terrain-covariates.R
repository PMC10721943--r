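plane_raster <- function(fx, fy, n = 9, cellsize = 1) {
  # z = fx * x + fy * y on an n x n grid (x east, y north)
  r <- grid_raster(matrix(0, n, n), cellsize = cellsize)
  cc <- cell_centers(r)
  vals <- matrix(NA_real_, n, n)
  vals[cbind(cc$row, cc$col)] <- fx * cc$x + fy * cc$y
  grid_raster(vals, cellsize = cellsize)
}

interior <- function(m) m[2:(nrow(m) - 1), 2:(ncol(m) - 1)]

test_that("slope matches closed forms on flat and inclined planes", {
  flat <- grid_raster(matrix(7, 6, 6))
  expect_true(all(compute_slope(flat)$values == 0))
  p1 <- plane_raster(1, 0)       # z = x, 1-m cells
  expect_equal(unique(as.vector(interior(compute_slope(p1)$values))), 45)
  p05 <- plane_raster(0.5, 0)
  expect_equal(unique(as.vector(interior(compute_slope(p05)$values))),
               atan(0.5) * 180 / pi, tolerance = 1e-10)
  expect_error(compute_slope(grid_raster(matrix(1, 2, 2))), "3 x 3")
})

test_that("aspect components match cardinal directions and unit identity", {
  # z rising to the south (fy = -1): faces north -> northness 1
  north_facing <- aspect_components(plane_raster(0, -1))
  expect_equal(unique(as.vector(interior(north_facing$northness$values))), 1)
  expect_equal(unique(as.vector(interior(north_facing$eastness$values))), 0)
  south_facing <- aspect_components(plane_raster(0, 1))
  expect_equal(unique(as.vector(interior(south_facing$northness$values))), -1)
  east_facing <- aspect_components(plane_raster(-1, 0))
  expect_equal(unique(as.vector(interior(east_facing$eastness$values))), 1)
  expect_equal(unique(as.vector(interior(east_facing$northness$values))), 0)
  # unit circle on sloped cells, zero on flats
  dem <- generate_dem(landscape_config(width_m = 30, height_m = 30,
                                       relief_amplitude_m = 5,
                                       roughness = 0.5, seed = 2))
  a <- aspect_components(dem)
  nsq <- a$northness$values^2 + a$eastness$values^2
  expect_true(all(abs(nsq - 1) < 1e-9 | nsq == 0))
  flat_a <- aspect_components(grid_raster(matrix(3, 5, 5)))
  expect_true(all(flat_a$northness$values == 0))
  expect_true(all(flat_a$eastness$values == 0))
})

test_that("geology distance classes follow the metre break points", {
  # single formation cell; neighbours at known centre-to-centre distances
  m <- matrix(0, 21, 21)
  m[11, 11] <- 1
  mask <- grid_raster(m, cellsize = 1)
  cls <- geology_distance_classes(mask)
  expect_equal(cls$values[11, 11], 1)   # inside: distance 0
  expect_equal(cls$values[11, 18], 2)   # 7 m away -> class 2
  expect_equal(cls$values[11, 12], 2)   # 1 m away: [1,10) -> class 2
  big <- matrix(0, 30, 120)
  big[15, 1] <- 1
  cls_big <- geology_distance_classes(grid_raster(big, cellsize = 1))
  expect_equal(cls_big$values[15, 6], 2)    # 5 m
  expect_equal(cls_big$values[15, 51], 3)   # 50 m
  expect_equal(cls_big$values[15, 111], 4)  # 110 m
  expect_error(geology_distance_classes(grid_raster(matrix(0, 4, 4))),
               "empty")
})

test_that("distance transform equals exhaustive nearest-cell search", {
  for (seed in 1:3) {
    m <- withr::with_seed(seed,
                          matrix(rbinom(40 * 35, 1, 0.05), 40, 35))
    if (!any(m == 1)) m[3, 7] <- 1
    got <- geology_distance_classes(grid_raster(m, cellsize = 2))
    d_oracle <- oracle_nearest_formation_distance(m, cellsize = 2)
    cls_oracle <- matrix(findInterval(d_oracle, c(1, 10, 100)) + 1L,
                         nrow(m), ncol(m))
    expect_equal(got$values, cls_oracle)
  }
})

test_that("soil colour index arithmetic and edge cases", {
  red <- grid_raster(matrix(c(0.3, 0.2, 0.4, 0), 2, 2))
  green <- grid_raster(matrix(c(0.1, 0.2, 0, 0), 2, 2))
  idx <- soil_color_index(red, green)
  expect_equal(idx$values[1, 1], 0.5)
  expect_equal(idx$values[2, 1], 0)    # R = G
  expect_equal(idx$values[1, 2], 1)    # G = 0
  expect_true(is.na(idx$values[2, 2])) # R + G = 0
  shifted <- grid_raster(matrix(1, 2, 2), xmin = 5)
  expect_error(soil_color_index(red, shifted), "same grid")
})

test_that("bilinear resampling is exact on constants, midpoints and planes", {
  coarse <- grid_raster(matrix(4.2, 3, 3), cellsize = 10)
  fine <- grid_raster(matrix(0, 30, 30), cellsize = 1)
  expect_equal(range(resample_bilinear(coarse, fine)$values), c(4.2, 4.2))
  # point equidistant from 4 coarse centres valued 0,0,10,10 -> 5
  vals <- matrix(c(0, 10, 0, 10), 2, 2)   # rows: north 0/0? columns split
  coarse2 <- grid_raster(matrix(c(0, 0, 10, 10), 2, 2), cellsize = 10)
  target_mid <- grid_raster(matrix(0, 1, 1), xmin = 9.5, ymin = 9.5,
                            cellsize = 1)
  expect_equal(resample_bilinear(coarse2, target_mid)$values[1, 1], 5)
  # target cell centre coincident with a coarse centre -> identity
  target_on <- grid_raster(matrix(0, 1, 1), xmin = 4.5, ymin = 4.5,
                           cellsize = 1)
  expect_equal(resample_bilinear(coarse2, target_on)$values[1, 1],
               coarse2$values[2, 1])
  # exact on affine surfaces over the interior
  cc <- cell_centers(grid_raster(matrix(0, 6, 6), cellsize = 10))
  plane_vals <- matrix(NA_real_, 6, 6)
  plane_vals[cbind(cc$row, cc$col)] <- 2 * cc$x - 3 * cc$y + 7
  coarse_plane <- grid_raster(plane_vals, cellsize = 10)
  fine_target <- grid_raster(matrix(0, 40, 40), xmin = 10, ymin = 10,
                             cellsize = 1)
  res <- resample_bilinear(coarse_plane, fine_target)
  fc <- cell_centers(res)
  expect_equal(res$values[cbind(fc$row, fc$col)],
               2 * fc$x - 3 * fc$y + 7, tolerance = 1e-9)
  outside <- grid_raster(matrix(0, 10, 10), xmin = 100, ymin = 0,
                         cellsize = 1)
  expect_error(resample_bilinear(coarse_plane, outside), "not covered")
})

test_that("covariate extraction drops unusable points with bookkeeping", {
  vals <- matrix(seq_len(100), 10, 10)
  vals[5, 5] <- NA
  stack <- make_stack(list(a = vals, b = vals * 2))
  cc <- cell_centers(stack$layers$a)
  # a point at a cell centre returns that cell's values exactly
  one <- extract_covariates(data.frame(x = cc$x[7], y = cc$y[7]), stack)
  expect_equal(one$data$a, cc$value[7])
  expect_equal(one$data$b, 2 * cc$value[7])
  pts <- withr::with_seed(4, data.frame(x = runif(100, 0, 10),
                                        y = runif(100, 0, 10)))
  res <- extract_covariates(pts, stack)
  expect_equal(nrow(res$data) + nrow(res$dropped), 100)
  expect_true(all(res$dropped$reason %in% c("nodata", "outside_extent")))
  far <- extract_covariates(data.frame(x = c(-5, 2.2), y = c(2, 3.3)), stack)
  expect_equal(far$dropped$reason, "outside_extent")
  expect_equal(nrow(far$data), 1)
  # point on the NA cell is dropped as nodata
  na_pt <- extract_covariates(data.frame(x = 4.5, y = 5.5), stack)
  expect_equal(na_pt$dropped$reason, "nodata")
})
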