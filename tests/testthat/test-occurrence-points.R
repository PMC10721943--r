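rect_poly <- function(x0, y0, w, h) {
  cbind(c(x0, x0 + w, x0 + w, x0), c(y0, y0, y0 + h, y0 + h))
}

test_that("greedy thinning matches enumeration on crafted and random sets", {
  collinear <- data.frame(x = 0:3, y = 0)
  expect_equal(thin_points(collinear, 2)$x, c(0, 2))
  expect_equal(thin_points(collinear, 0), collinear)
  coincident <- data.frame(x = rep(1, 10), y = rep(2, 10))
  expect_equal(nrow(thin_points(coincident, 0.5)), 1)
  for (seed in 1:5) {
    pts <- withr::with_seed(seed,
      data.frame(x = runif(150, 0, 100), y = runif(150, 0, 100)))
    got <- thin_points(pts, 12)
    expect_equal(got, oracle_greedy_thin(pts, 12),
                 ignore_attr = "row.names")
    expect_gte(min(dist(cbind(got$x, got$y))), 12)
  }
})

test_that("polygon-to-point generation follows the area and grid rules", {
  # 3 x 5 m rectangle (15 m2 < 20 m2): one centroid point
  small <- polygon_to_points(list(rect_poly(100, 40, 3, 5)))
  expect_equal(nrow(small), 1)
  expect_equal(small$x, 101.5)
  expect_equal(small$y, 42.5)
  # 30 x 30 m grid-aligned square: 9 covered 10-m centres, thinned to 1
  square <- rect_poly(0, 0, 30, 30)
  unthinned <- polygon_to_points(list(square), thin_m = 0)
  expect_equal(nrow(unthinned), 9)
  thinned <- polygon_to_points(list(square), thin_m = 40)
  expect_equal(nrow(thinned), 1)
  # 10 x 90 m strip: 9 centroids 10 m apart; greedy 40-m walk keeps 3
  strip <- polygon_to_points(list(rect_poly(0, 0, 10, 90)))
  expect_equal(nrow(strip), 3)
  expect_equal(sort(strip$y), c(5, 45, 85))
  # a sliver above the area cut-off but covering no cell centre falls back
  # to its centroid, so every polygon contributes
  sliver <- rect_poly(2.4, 0, 0.22, 95)   # ~21 m2, x centres at 5,15,...
  res <- polygon_to_points(list(sliver))
  expect_equal(nrow(res), 1)
  expect_equal(res$source, "polygon_derived")
})

test_that("background points are uniform over the valid mask", {
  one_cell <- matrix(0, 5, 5)
  one_cell[2, 3] <- 1
  # exceeding the density cap warns but still returns the draw
  expect_warning(
    bg1 <- generate_background(grid_raster(one_cell), 40, seed = 2),
    "density")
  expect_true(all(bg1$x > 2 & bg1$x < 3 & bg1$y > 3 & bg1$y < 4))
  n_req <- 4333
  bg <- generate_background(grid_raster(matrix(1, 50, 50), cellsize = 10),
                            n_req, seed = 3)
  expect_equal(nrow(bg), n_req)
  qx <- cut(bg$x, seq(0, 500, 100)); qy <- cut(bg$y, seq(0, 500, 100))
  expect_gt(chisq.test(as.vector(table(qx, qy)))$p.value, 0.01)
  expect_error(generate_background(grid_raster(matrix(0, 3, 3)), 5),
               "no valid cells")
})

test_that("absence points tile surveyed-minus-detected area at 20 m", {
  cells <- data.frame(cell_id = 1, x_min = 0, y_min = 0, detected = 0)
  abs1 <- absence_from_survey(cells, cell_size_m = 100)
  expect_equal(nrow(abs1), 25)
  detected_cell <- data.frame(cell_id = 1, x_min = 0, y_min = 0,
                              detected = 1)
  expect_equal(nrow(absence_from_survey(detected_cell, cell_size_m = 100)),
               0)
  # a detection strip masking out one 20-m row leaves 20 points
  strip <- list(rect_poly(-1, 79, 102, 22))
  abs2 <- absence_from_survey(data.frame(cell_id = 1, x_min = 0, y_min = 0,
                                         detected = 1),
                              cell_size_m = 100,
                              detection_polygons = strip)
  expect_equal(nrow(abs2), 20)
  expect_true(all(abs2$label == "absence" & abs2$source == "survey_absence"))
})

test_that("exclusion filter implements a strict 'closer than' rule", {
  pres <- data.frame(x = 0, y = 0)
  cand <- data.frame(x = c(50, 100, 170), y = 0)
  kept <- exclusion_filter(cand, pres, 100)
  expect_equal(kept$x, c(100, 170))   # exactly 100 m is kept
  expect_equal(exclusion_filter(cand, pres[0, ], 100), cand)
})

test_that("presence assembly merges sources, thins at 2 m and keeps counts", {
  po <- data.frame(x = c(0, 10, 20), y = 0, label = "presence",
                   source = "point_obs")
  pp <- data.frame(x = c(0, 30), y = c(0, 0), label = "presence",
                   source = "polygon_derived")
  merged <- assemble_presences(po, pp, thin_m = 2)
  expect_equal(nrow(merged), 4)    # duplicate of (0,0) collapsed
  counts <- attr(merged, "source_counts")
  expect_equal(unname(counts["point_obs"]), 3L)
  expect_equal(unname(counts["polygon_derived"]), 1L)
  alone <- assemble_presences(po, pp[0, ], thin_m = 2)
  expect_equal(nrow(alone), 3)
})

test_that("label/source pairings are validated", {
  expect_error(occurrence_points(1, 1, "presence", "random_background"),
               "invalid label/source")
  ok <- occurrence_points(1:2, 1:2, "background", "random_background")
  expect_equal(nrow(ok), 2)
})

test_that("train/validation split is stratified, seeded and exhaustive", {
  pts <- data.frame(point_id = 1:1200,
                    label = rep(c("presence", "background"),
                                c(900, 300)))
  sp <- split_train_validation(pts, 2 / 3, seed = 7)
  expect_equal(sum(sp$train$label == "presence"), 600)
  expect_equal(sum(sp$validation$label == "presence"), 300)
  expect_equal(sum(sp$train$label == "background"), 200)
  sp2 <- split_train_validation(pts, 2 / 3, seed = 7)
  expect_identical(sp$train$point_id, sp2$train$point_id)
  expect_equal(sort(c(sp$train$point_id, sp$validation$point_id)),
               pts$point_id)
  expect_length(intersect(sp$train$point_id, sp$validation$point_id), 0)
  few <- data.frame(label = c("presence", "presence", "background",
                              "background", "background"))
  expect_error(split_train_validation(few), "at least 3")
})
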