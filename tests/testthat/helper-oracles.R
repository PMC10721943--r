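# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths: pair/rank enumeration, ray casting,
# exhaustive nearest-cell searches.

oracle_auc_roc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

oracle_auc_pr <- function(scores, labels) {
  # average precision with tie blocks scored at the block end
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  ap <- 0
  i <- 1
  tp <- 0; seen <- 0
  while (i <= length(s)) {
    j <- i
    while (j < length(s) && s[j + 1] == s[i]) j <- j + 1
    block_pos <- sum(l[i:j])
    tp <- tp + block_pos
    seen <- seen + (j - i + 1)
    ap <- ap + block_pos * tp / seen
    i <- j + 1
  }
  ap / sum(l)
}

oracle_cliffs_delta <- function(x, y) {
  gt <- 0; lt <- 0
  for (a in x) for (b in y) {
    if (a > b) gt <- gt + 1
    if (a < b) lt <- lt + 1
  }
  (gt - lt) / (length(x) * length(y))
}

oracle_greedy_thin <- function(points, min_dist) {
  kept <- integer()
  for (i in seq_len(nrow(points))) {
    ok <- TRUE
    for (k in kept) {
      d <- sqrt((points$x[i] - points$x[k])^2 +
                  (points$y[i] - points$y[k])^2)
      if (d < min_dist) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  points[kept, , drop = FALSE]
}

oracle_point_in_polygon <- function(poly, px, py) {
  # even-odd ray casting, one point at a time
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- !inside
    j <- i
  }
  inside
}

oracle_nearest_formation_distance <- function(mask_vals, cellsize) {
  # exhaustive nearest formation-cell search, centre to centre
  nr <- nrow(mask_vals); nc <- ncol(mask_vals)
  form <- which(mask_vals > 0, arr.ind = TRUE)
  out <- matrix(Inf, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    d2 <- (form[, 1] - i)^2 + (form[, 2] - j)^2
    out[i, j] <- sqrt(min(d2)) * cellsize
  }
  out
}

oracle_fixed_sensitivity_threshold <- function(scores, target) {
  # scan every achievable candidate, keep the largest meeting the target
  cand <- sort(unique(c(0, 1, scores)))
  best <- NA_real_
  for (t in cand) {
    if (mean(scores >= t) >= target) best <- max(best, t, na.rm = TRUE)
  }
  best
}

# small aligned stack on an n x n unit grid with named constant or supplied
# layers, for model and extraction tests
make_stack <- function(layers, cellsize = 1, xmin = 0, ymin = 0) {
  covariate_stack(lapply(layers, function(v) {
    grid_raster(v, xmin = xmin, ymin = ymin, cellsize = cellsize)
  }))
}

# separable two-class training table: covariate `a` fully separates labels
make_separable_train <- function(n_per_class = 30, seed = 42) {
  withr::with_seed(seed, {
    data.frame(
      label = rep(c("presence", "background"), each = n_per_class),
      source = rep(c("point_obs", "random_background"), each = n_per_class),
      a = c(runif(n_per_class, 1, 2), runif(n_per_class, -2, -1)),
      b = rnorm(2 * n_per_class)
    )
  })
}
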