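#' Construct an occurrence point table
#'
#' @param x,y coordinates (m).
#' @param label one of `"presence"`, `"background"`, `"absence"`.
#' @param source provenance: `"point_obs"`, `"polygon_derived"`,
#'   `"random_background"` or `"survey_absence"`. Label/source pairings are
#'   checked (presences come from observations or polygons, absences from
#'   surveys, background from random generation).
#' @return A data.frame with `point_id`, `x`, `y`, `label`, `source`.
#' @export
occurrence_points <- function(x, y, label, source) {
  allowed <- list(presence = c("point_obs", "polygon_derived"),
                  background = "random_background",
                  absence = "survey_absence")
  label <- rep_len(label, length(x))
  source <- rep_len(source, length(x))
  for (i in seq_along(label)) {
    if (!label[i] %in% names(allowed) ||
        !source[i] %in% allowed[[label[i]]])
      stop(sprintf("invalid label/source pair: %s/%s", label[i], source[i]),
           call. = FALSE)
  }
  data.frame(point_id = seq_along(x), x = x, y = y,
             label = label, source = source)
}

#' Greedy spatial thinning
#'
#' Sequential scan in input order: a point is kept iff it lies at least
#' `min_dist_m` from every point already kept. The result is therefore an
#' order-stable subset whose pairwise distances are all >= `min_dist_m`
#' ("closer than d" is removed; ties at exactly d are kept). Because the
#' outcome depends on input order, an optional seeded shuffle is available
#' for sensitivity checks.
#'
#' @param points data.frame with `x`, `y` (other columns carried through).
#' @param min_dist_m minimum allowed pairwise distance (>= 0).
#' @param shuffle if `TRUE`, scan in a seeded random order instead of input
#'   order (output still sorted back to input order).
#' @param seed seed for the optional shuffle.
#' @return The kept subset of `points`.
#' @export
thin_points <- function(points, min_dist_m, shuffle = FALSE, seed = 1L) {
  if (min_dist_m < 0) stop("min_dist_m must be >= 0", call. = FALSE)
  n <- nrow(points)
  if (n == 0 || min_dist_m == 0) return(points)
  ord <- if (shuffle) with_seed(seed, sample.int(n)) else seq_len(n)
  xs <- points$x[ord]; ys <- points$y[ord]
  kept <- logical(n)
  kept[1L] <- TRUE
  ki <- 1L
  for (i in seq_len(n)[-1L]) {
    d2 <- (xs[ki] - xs[i])^2 + (ys[ki] - ys[i])^2
    if (min(d2) >= min_dist_m^2) {
      kept[i] <- TRUE
      ki <- c(ki, i)
    }
  }
  out <- points[sort(ord[kept]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# 10-m (or grid_m) raster cell centres covered by a polygon; the grid is
# anchored at `origin` so repeated runs and neighbouring polygons share cells
covered_cell_centers <- function(poly, grid_m, origin = c(0, 0)) {
  rx <- range(poly[, 1]); ry <- range(poly[, 2])
  cxs <- seq(floor((rx[1] - origin[1]) / grid_m),
             ceiling((rx[2] - origin[1]) / grid_m))
  cys <- seq(floor((ry[1] - origin[2]) / grid_m),
             ceiling((ry[2] - origin[2]) / grid_m))
  centers <- expand.grid(
    x = origin[1] + (cxs + 0.5) * grid_m,
    y = origin[2] + (cys + 0.5) * grid_m
  )
  # enumerate south-to-north, west-to-east for a deterministic scan order
  centers <- centers[order(centers$y, centers$x), , drop = FALSE]
  inside <- mgcv::in.out(rbind(poly, poly[1, ]),
                         as.matrix(centers))
  centers[inside, , drop = FALSE]
}

#' Presence points from mapped subpopulation polygons
#'
#' Converts field-mapped occupancy polygons into presence points without
#' letting large polygons overwhelm the point observations. Polygons with
#' area below `small_area_m2` contribute exactly their centroid. Larger
#' polygons are rasterized on a `grid_m` grid (a cell is covered when its
#' centre falls inside the polygon) and contribute one point per covered
#' cell centre; those grid-derived points are then thinned so no two are
#' closer than `thin_m`. A large polygon that covers no cell centre (a
#' thin sliver), or whose grid points are all eliminated by thinning
#' against earlier polygons, falls back to its centroid so that every
#' polygon contributes at least one point.
#'
#' @param polygons list of two-column vertex matrices.
#' @param small_area_m2 area cut-off below which only the centroid is used
#'   (default 20).
#' @param grid_m rasterization grid for large polygons (default 10).
#' @param thin_m minimum pairwise distance among grid-derived points
#'   (default 40).
#' @param origin anchor of the rasterization grid.
#' @return A data.frame of presence points (`x`, `y`, `label`, `source`,
#'   `polygon_id`).
#' @export
polygon_to_points <- function(polygons, small_area_m2 = 20, grid_m = 10,
                              thin_m = 40, origin = c(0, 0)) {
  cent_pts <- list(); grid_pts <- list()
  for (i in seq_along(polygons)) {
    poly <- polygons[[i]]
    if (!is.matrix(poly) || nrow(poly) < 3 ||
        any(!is.finite(poly))) {
      warning("skipping invalid polygon ", i, call. = FALSE)
      next
    }
    if (polygon_area(poly) < small_area_m2) {
      ctr <- polygon_centroid(poly)
      cent_pts[[length(cent_pts) + 1L]] <-
        data.frame(x = ctr[1], y = ctr[2], polygon_id = i)
    } else {
      cc <- covered_cell_centers(poly, grid_m, origin)
      if (nrow(cc) == 0) {           # sliver: centroid fallback
        ctr <- polygon_centroid(poly)
        cc <- data.frame(x = ctr[1], y = ctr[2])
      }
      cc$polygon_id <- i
      grid_pts[[length(grid_pts) + 1L]] <- cc
    }
  }
  gp <- if (length(grid_pts)) do.call(rbind, grid_pts) else
    data.frame(x = numeric(), y = numeric(), polygon_id = integer())
  gp <- thin_points(gp, thin_m)
  # guarantee every rasterized polygon still contributes a point
  lost <- setdiff(unique(unlist(lapply(grid_pts, `[[`, "polygon_id"))),
                  gp$polygon_id)
  for (i in lost) {
    ctr <- polygon_centroid(polygons[[i]])
    gp <- rbind(gp, data.frame(x = ctr[1], y = ctr[2], polygon_id = i))
  }
  cp <- if (length(cent_pts)) do.call(rbind, cent_pts) else
    data.frame(x = numeric(), y = numeric(), polygon_id = integer())
  out <- rbind(cp, gp)
  if (!nrow(out))
    return(data.frame(point_id = integer(), x = numeric(), y = numeric(),
                      label = character(), source = character(),
                      polygon_id = integer()))
  data.frame(point_id = seq_len(nrow(out)), x = out$x, y = out$y,
             label = "presence", source = "polygon_derived",
             polygon_id = out$polygon_id)
}

#' Random background points over the valid study area
#'
#' Draws `n` points uniformly over the non-missing cells of a validity
#' mask (uniform cell choice, then uniform position within the cell), the
#' standard presence-background contrast sample.
#'
#' @param mask a `grid_raster`; cells that are finite and non-zero are
#'   valid. Use a constant raster for "everywhere valid".
#' @param n number of points (>= 1).
#' @param seed integer seed.
#' @param max_density_per_km2 soft cap; exceeding it warns (the draw still
#'   happens) because extreme background densities slow model fitting
#'   without adding information.
#' @return A data.frame of background points.
#' @export
generate_background <- function(mask, n, seed = 1L,
                                max_density_per_km2 = 1e6) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  cc <- cell_centers(mask)
  valid <- which(is.finite(cc$value) & cc$value != 0)
  if (!length(valid)) stop("mask has no valid cells", call. = FALSE)
  area_km2 <- length(valid) * mask$cellsize^2 / 1e6
  if (n / area_km2 > max_density_per_km2)
    warning(sprintf("background density %.3g/km2 exceeds cap %.3g/km2",
                    n / area_km2, max_density_per_km2), call. = FALSE)
  with_seed(substream_seed(seed, "background"), {
    idx <- valid[sample.int(length(valid), n, replace = TRUE)]
    data.frame(
      point_id = seq_len(n),
      x = cc$x[idx] + stats::runif(n, -0.5, 0.5) * mask$cellsize,
      y = cc$y[idx] + stats::runif(n, -0.5, 0.5) * mask$cellsize,
      label = "background", source = "random_background"
    )
  })
}

#' True-absence points from surveyed cells
#'
#' Surveyed cells where the species was not found are treated as true
#' absences. To avoid flooding the models with near-duplicate absences,
#' the surveyed-minus-detected area is rasterized at `grid_m` resolution
#' and one point is placed at the centroid of each remaining cell.
#'
#' @param survey_cells a `survey_cells` data.frame (`x_min`, `y_min`,
#'   `detected`) as from [generate_survey_cells()].
#' @param cell_size_m survey cell edge length (default 50).
#' @param detection_polygons optional list of polygons (mapped detections)
#'   to mask out of surveyed cells; cells flagged `detected` are masked out
#'   entirely in addition.
#' @param grid_m absence grid resolution (default 20).
#' @param origin anchor of the absence grid.
#' @return A data.frame of absence points.
#' @export
absence_from_survey <- function(survey_cells, cell_size_m = 50,
                                detection_polygons = list(), grid_m = 20,
                                origin = c(0, 0)) {
  if (!nrow(survey_cells))
    return(data.frame(point_id = integer(), x = numeric(), y = numeric(),
                      label = character(), source = character()))
  pts <- list()
  for (i in seq_len(nrow(survey_cells))) {
    # a detected cell with no mapped detection polygons is excluded whole
    if (survey_cells$detected[i] == 1 && !length(detection_polygons)) next
    x0 <- survey_cells$x_min[i]; y0 <- survey_cells$y_min[i]
    cxs <- seq(floor((x0 - origin[1]) / grid_m),
               ceiling((x0 + cell_size_m - origin[1]) / grid_m) - 1L)
    cys <- seq(floor((y0 - origin[2]) / grid_m),
               ceiling((y0 + cell_size_m - origin[2]) / grid_m) - 1L)
    g <- expand.grid(x = origin[1] + (cxs + 0.5) * grid_m,
                     y = origin[2] + (cys + 0.5) * grid_m)
    g <- g[g$x >= x0 & g$x <= x0 + cell_size_m &
             g$y >= y0 & g$y <= y0 + cell_size_m, , drop = FALSE]
    pts[[length(pts) + 1L]] <- g
  }
  out <- if (length(pts)) do.call(rbind, pts) else
    data.frame(x = numeric(), y = numeric())
  out <- unique(out)
  if (length(detection_polygons) && nrow(out)) {
    inside <- points_in_polygons(detection_polygons, out$x, out$y)
    out <- out[!inside, , drop = FALSE]
  }
  if (!nrow(out))
    return(data.frame(point_id = integer(), x = numeric(), y = numeric(),
                      label = character(), source = character()))
  rownames(out) <- NULL
  data.frame(point_id = seq_len(nrow(out)), x = out$x, y = out$y,
             label = "absence", source = "survey_absence")
}

#' Exclude candidates near presences
#'
#' Removes background/absence candidates lying closer than `radius_m` to
#' any presence ("closer than" is strict: a candidate at exactly
#' `radius_m` is kept). Keeping non-presence points well away from
#' presences sharpens the habitat contrast the models learn.
#'
#' @param candidates data.frame with `x`, `y`.
#' @param presences data.frame with `x`, `y`.
#' @param radius_m exclusion radius (default 100).
#' @return The retained subset of `candidates`.
#' @export
exclusion_filter <- function(candidates, presences, radius_m = 100) {
  if (radius_m < 0) stop("radius_m must be >= 0", call. = FALSE)
  if (!nrow(candidates) || !nrow(presences) || radius_m == 0)
    return(candidates)
  keep <- rep(TRUE, nrow(candidates))
  r2 <- radius_m^2
  chunk <- 2000L
  for (start in seq(1L, nrow(candidates), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(candidates))
    d2 <- outer(candidates$x[idx], presences$x, "-")^2 +
      outer(candidates$y[idx], presences$y, "-")^2
    keep[idx] <- apply(d2, 1L, min) >= r2
  }
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge and thin the presence set
#'
#' Merges direct point observations with polygon-derived points (point
#' observations first, so thinning favours them), then thins to a
#' `thin_m` minimum pairwise distance so that dense clusters of
#' observations do not dominate the training sample.
#'
#' @param point_obs data.frame of presences with source `"point_obs"`.
#' @param polygon_points data.frame of presences with source
#'   `"polygon_derived"` (as from [polygon_to_points()]).
#' @param thin_m minimum pairwise distance (default 2).
#' @return The merged, thinned presence data.frame; counts by source are
#'   attached as attribute `"source_counts"`.
#' @export
assemble_presences <- function(point_obs, polygon_points, thin_m = 2) {
  cols <- c("x", "y", "label", "source")
  merged <- rbind(point_obs[, cols, drop = FALSE],
                  polygon_points[, cols, drop = FALSE])
  merged <- thin_points(merged, thin_m)
  merged$point_id <- seq_len(nrow(merged))
  merged <- merged[, c("point_id", cols)]
  attr(merged, "source_counts") <- table(merged$source)
  merged
}

#' Stratified train/validation split
#'
#' Splits points into training and validation sets at `train_fraction`
#' within each label (presence, background, absence), so class balance is
#' identical on both sides. The per-label training count is
#' `round(n * train_fraction)`, clamped so both sides keep at least one
#' point. Seeded and reproducible.
#'
#' @param points data.frame with a `label` column.
#' @param train_fraction fraction assigned to training (default 2/3).
#' @param seed integer seed.
#' @return A list with `train` and `validation` data.frames.
#' @export
split_train_validation <- function(points, train_fraction = 2 / 3,
                                   seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie in (0, 1)", call. = FALSE)
  counts <- table(points$label)
  if (any(counts < 3))
    stop("each label needs at least 3 points to split", call. = FALSE)
  train_idx <- with_seed(substream_seed(seed, "split"), {
    unlist(lapply(names(counts), function(lb) {
      idx <- which(points$label == lb)
      n_train <- min(max(round(length(idx) * train_fraction), 1L),
                     length(idx) - 1L)
      sample(idx, n_train)
    }))
  })
  train_idx <- sort(train_idx)
  list(train = points[train_idx, , drop = FALSE],
       validation = points[-train_idx, , drop = FALSE])
}
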