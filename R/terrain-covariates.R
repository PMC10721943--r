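#' Aligned covariate stack
#'
#' Bundles named covariate layers that share grid shape, origin and cell
#' size. The stack is the single object handed to extraction and raster
#' prediction, so layer alignment is checked once, here.
#'
#' @param layers named list of `grid_raster` objects.
#' @return A `covariate_stack` with `layers` and `layer_names`.
#' @export
covariate_stack <- function(layers) {
  if (is.null(names(layers)) || any(names(layers) == ""))
    stop("all layers must be named", call. = FALSE)
  base <- layers[[1]]
  for (nm in names(layers))
    stopifnot_same_grid(base, layers[[nm]], paste0("layer '", nm, "' and base"))
  structure(list(layers = layers, layer_names = names(layers)),
            class = "covariate_stack")
}

#' @export
print.covariate_stack <- function(x, ...) {
  b <- x$layers[[1]]
  cat(sprintf("<covariate_stack> %d layers on %d x %d grid @ %g m\n",
              length(x$layers), nrow(b$values), ncol(b$values), b$cellsize))
  cat(" ", paste(x$layer_names, collapse = ", "), "\n")
  invisible(x)
}

# Horn 3x3 gradients with edge replication; returns east (dz/dx) and
# north (dz/dy) components in rise per metre
horn_gradients <- function(dem) {
  m <- dem$values
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 3 || nc < 3) stop("raster must be at least 3 x 3", call. = FALSE)
  ri <- c(1L, seq_len(nr), nr)
  ci <- c(1L, seq_len(nc), nc)
  p <- m[ri, ci]
  sub <- function(dr, dc) p[(2L + dr):(nr + 1L + dr), (2L + dc):(nc + 1L + dc)]
  nw <- sub(-1L, -1L); n_ <- sub(-1L, 0L); ne <- sub(-1L, 1L)
  w_ <- sub(0L, -1L);                     e_ <- sub(0L, 1L)
  sw <- sub(1L, -1L);  s_ <- sub(1L, 0L); se <- sub(1L, 1L)
  cs <- dem$cellsize
  list(
    dzdx = ((ne + 2 * e_ + se) - (nw + 2 * w_ + sw)) / (8 * cs),
    dzdy = ((nw + 2 * n_ + ne) - (sw + 2 * s_ + se)) / (8 * cs)
  )
}

#' Terrain slope in degrees
#'
#' Slope from Horn's 3x3 finite-difference stencil (the convention of
#' standard GIS slope tools), with border cells handled by edge
#' replication: `slope = atan(|gradient|)` in degrees.
#'
#' @param dem a `grid_raster` of elevations (m), at least 3 x 3.
#' @return A `grid_raster` of slopes in degrees.
#' @export
compute_slope <- function(dem) {
  g <- horn_gradients(dem)
  grid_raster(atan(sqrt(g$dzdx^2 + g$dzdy^2)) * 180 / pi,
              dem$xmin, dem$ymin, dem$cellsize)
}

#' Northness and eastness of terrain aspect
#'
#' Aspect is the compass direction a slope faces (downslope direction),
#' measured clockwise from north, derived from the same Horn gradients as
#' [compute_slope()]. Because aspect is circular it enters models as its
#' cosine (northness) and sine (eastness):
#' `northness = cos(aspect * pi / 180)`, `eastness = sin(aspect * pi / 180)`.
#' Flat cells, where aspect is undefined, get northness = eastness = 0 so
#' they contribute no directional signal.
#'
#' @param dem a `grid_raster` of elevations (m), at least 3 x 3.
#' @return A list with `northness` and `eastness` `grid_raster`s in [-1, 1].
#' @export
aspect_components <- function(dem) {
  g <- horn_gradients(dem)
  mag <- sqrt(g$dzdx^2 + g$dzdy^2)
  flat <- !is.na(mag) & mag == 0
  northness <- -g$dzdy / mag
  eastness <- -g$dzdx / mag
  northness[flat] <- 0
  eastness[flat] <- 0
  list(
    northness = grid_raster(northness, dem$xmin, dem$ymin, dem$cellsize),
    eastness = grid_raster(eastness, dem$xmin, dem$ymin, dem$cellsize)
  )
}

# Felzenszwalb & Huttenlocher exact 1-D squared distance transform
dt_1d <- function(f) {
  n <- length(f)
  if (n == 1L) return(f)
  d <- numeric(n); v <- integer(n); z <- numeric(n + 1L)
  k <- 1L; v[1L] <- 1L; z[1L] <- -Inf; z[2L] <- Inf
  for (q in 2:n) {
    s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
    while (s <= z[k]) {
      k <- k - 1L
      s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- s
    z[k + 1L] <- Inf
  }
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1L] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

# exact Euclidean distance (metres, centre-to-centre) to the nearest TRUE cell
distance_transform <- function(mask_vals, cellsize) {
  big <- 1e12
  f <- ifelse(mask_vals > 0, 0, big)
  f <- apply(f, 2L, dt_1d)                # along columns (y)
  f <- t(apply(f, 1L, dt_1d))             # then along rows (x)
  sqrt(f) * cellsize
}

#' Ordinal geology distance classes
#'
#' Computes the exact Euclidean distance (cell centre to nearest formation
#' cell centre; 0 inside the formation) and bins it into four ordinal
#' classes: class 1 for distances in [0, 1) m — i.e. on or immediately
#' adjacent to the formation — class 2 for [1, 10) m, class 3 for
#' [10, 100) m and class 4 beyond 100 m. The ordinal coding reflects the
#' steeply decaying relevance of the formation with distance while keeping
#' a single numeric feature.
#'
#' @param mask a 0/1 `grid_raster`; must contain at least one formation cell.
#' @param breaks_m upper class edges in metres (default `c(1, 10, 100)`).
#' @return A `grid_raster` of integer classes 1..4.
#' @export
geology_distance_classes <- function(mask, breaks_m = c(1, 10, 100)) {
  if (!any(mask$values > 0, na.rm = TRUE))
    stop("formation mask is empty: all distances undefined", call. = FALSE)
  d <- distance_transform(mask$values, mask$cellsize)
  cls <- matrix(findInterval(d, breaks_m) + 1L, nrow(d), ncol(d))
  grid_raster(cls, mask$xmin, mask$ymin, mask$cellsize)
}

#' Soil colour index
#'
#' The normalized red-green difference `(R - G)/(R + G)`, which is high on
#' reddish soils and near zero on gray, spectrally flat soils; used here to
#' discriminate the pale shale-derived surface the species occupies. Cells
#' where `R + G = 0` are set to `NA`.
#'
#' @param red,green aligned reflectance `grid_raster`s (values >= 0).
#' @return A `grid_raster` in [-1, 1].
#' @export
soil_color_index <- function(red, green) {
  stopifnot_same_grid(red, green, "red and green bands")
  s <- red$values + green$values
  idx <- (red$values - green$values) / s
  idx[s == 0] <- NA_real_
  grid_raster(idx, red$xmin, red$ymin, red$cellsize)
}

#' Bilinear resampling of a coarse raster onto a fine grid
#'
#' Cell-centre bilinear interpolation from the four nearest coarse cell
#' centres, used to align a coarse layer (e.g. 800-m precipitation) with
#' the fine analysis grid without introducing sharp cell transitions.
#' Outside the hull of coarse cell centres, edge values are extended
#' (constant extrapolation), but the target extent must lie within the
#' coarse raster's footprint.
#'
#' @param coarse the coarse `grid_raster`.
#' @param target a `grid_raster` (or `covariate_stack` layer) defining the
#'   output grid; its values are ignored.
#' @return A `grid_raster` on the target grid.
#' @export
resample_bilinear <- function(coarse, target) {
  et <- raster_extent(target); ec <- raster_extent(coarse)
  if (et["xmin"] < ec["xmin"] - 1e-9 || et["xmax"] > ec["xmax"] + 1e-9 ||
      et["ymin"] < ec["ymin"] - 1e-9 || et["ymax"] > ec["ymax"] + 1e-9)
    stop("target extent is not covered by the coarse raster", call. = FALSE)
  m <- coarse$values
  nrc <- nrow(m); ncc <- ncol(m)
  nrt <- nrow(target$values); nct <- ncol(target$values)
  # fractional coarse column index (0-based at first centre) per target col
  xt <- target$xmin + (seq_len(nct) - 0.5) * target$cellsize
  u <- (xt - coarse$xmin) / coarse$cellsize - 0.5
  u <- pmin(pmax(u, 0), ncc - 1)
  c0 <- pmin(floor(u) + 1L, ncc); c1 <- pmin(c0 + 1L, ncc)
  fx <- u - (c0 - 1L)
  # fractional coarse row index per target row (rows count from north)
  yt <- (target$ymin + nrt * target$cellsize) -
    (seq_len(nrt) - 0.5) * target$cellsize
  v <- ((coarse$ymin + nrc * coarse$cellsize) - yt) / coarse$cellsize - 0.5
  v <- pmin(pmax(v, 0), nrc - 1)
  r0 <- pmin(floor(v) + 1L, nrc); r1 <- pmin(r0 + 1L, nrc)
  fy <- v - (r0 - 1L)
  out <- (1 - fy) %o% (1 - fx) * m[r0, c0, drop = FALSE] +
    (1 - fy) %o% fx       * m[r0, c1, drop = FALSE] +
    fy %o% (1 - fx)       * m[r1, c0, drop = FALSE] +
    fy %o% fx             * m[r1, c1, drop = FALSE]
  grid_raster(out, target$xmin, target$ymin, target$cellsize)
}

#' Extract covariate values at points
#'
#' Containing-cell lookup of every stack layer at each point. Points
#' falling outside the stack extent, or on a cell that is missing in any
#' layer, are excluded from the returned table and reported in `dropped`
#' with a reason — they cannot enter modelling.
#'
#' @param points data.frame with `x`, `y` and optionally `point_id`,
#'   `label`, `source` columns (carried through).
#' @param stack a [covariate_stack()].
#' @return A list: `data` (one row per usable point: id/label columns plus
#'   one column per covariate) and `dropped` (point_id, reason).
#' @export
extract_covariates <- function(points, stack) {
  if (!nrow(points)) {
    return(list(data = points, dropped = data.frame(point_id = integer(),
                                                    reason = character())))
  }
  if (is.null(points$point_id)) points$point_id <- seq_len(nrow(points))
  vals <- sapply(stack$layers, function(l)
    raster_value_at(l, points$x, points$y))
  vals <- matrix(vals, nrow = nrow(points),
                 dimnames = list(NULL, stack$layer_names))
  base <- stack$layers[[1]]
  idx <- cell_index(base, points$x, points$y)
  outside <- is.na(idx$row)
  nodata <- !outside & apply(vals, 1L, function(r) any(!is.finite(r)))
  keep <- !outside & !nodata
  dropped <- data.frame(
    point_id = points$point_id[!keep],
    reason = ifelse(outside[!keep], "outside_extent", "nodata")
  )
  keep_cols <- intersect(c("point_id", "label", "source", "x", "y"),
                         names(points))
  data <- cbind(points[keep, keep_cols, drop = FALSE],
                as.data.frame(vals[keep, , drop = FALSE]))
  rownames(data) <- NULL
  list(data = data, dropped = dropped)
}
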