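#' @title Simple polygon utilities
#' @description Polygons are represented as two-column matrices of vertex
#'   coordinates (x, y) in metres, unclosed (the closing edge is implicit).
#'   Sets of polygons are plain lists of such matrices. All geometry is
#'   planar Euclidean, matching the package's projected-metres contract.
#' @name polygon-utils
NULL

#' Polygon area (shoelace formula)
#'
#' @param poly two-column matrix of vertices.
#' @return Area in square metres (always non-negative).
#' @export
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Polygon centroid
#'
#' Area-weighted centroid of a simple polygon.
#'
#' @param poly two-column matrix of vertices.
#' @return Length-2 numeric vector `(x, y)`.
#' @export
polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(2:n, 1)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(mean(x), mean(y)))  # degenerate: vertex mean
  c(sum((x + x[j]) * cr) / (6 * a), sum((y + y[j]) * cr) / (6 * a))
}

#' Test points against a set of polygons
#'
#' A point is "inside" if it falls in at least one polygon of the set
#' (overlaps are unioned, not toggled).
#'
#' @param polys list of two-column vertex matrices.
#' @param x,y point coordinates.
#' @return Logical vector, one element per point.
#' @export
points_in_polygons <- function(polys, x, y) {
  pts <- cbind(x, y)
  inside <- rep(FALSE, length(x))
  for (p in polys) {
    if (all(inside)) break
    todo <- which(!inside)
    inside[todo] <- mgcv::in.out(rbind(p, p[1, ]), pts[todo, , drop = FALSE])
  }
  inside
}

# pairwise minimum distance >= d check helper (used in invariant tests too)
min_pairwise_distance <- function(x, y) {
  if (length(x) < 2) return(Inf)
  min(stats::dist(cbind(x, y)))
}

#' Write points or polygons as GeoJSON
#'
#' Points are written as a `FeatureCollection` of `Point` features carrying
#' any extra columns of `data` as properties; polygons as `Polygon` features.
#'
#' @param data for points, a data.frame with `x` and `y` columns; for
#'   polygons, a list of two-column vertex matrices.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_geojson <- function(data, path) {
  if (is.data.frame(data)) {
    props <- data[setdiff(names(data), c("x", "y"))]
    feats <- lapply(seq_len(nrow(data)), function(i) {
      list(type = "Feature",
           geometry = list(type = "Point",
                           coordinates = c(data$x[i], data$y[i])),
           properties = as.list(props[i, , drop = FALSE]))
    })
  } else {
    feats <- lapply(seq_along(data), function(i) {
      ring <- rbind(data[[i]], data[[i]][1, , drop = FALSE])
      list(type = "Feature",
           geometry = list(type = "Polygon",
                           coordinates = list(unname(apply(ring, 1, c,
                                                           simplify = FALSE)))),
           properties = list(id = i))
    })
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a GeoJSON FeatureCollection written by [write_geojson()]
#'
#' @param path input file.
#' @return A data.frame of points (with properties) or a list of polygon
#'   vertex matrices, depending on the geometry type found.
#' @export
read_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  feats <- gj$features
  if (!length(feats)) return(data.frame(x = numeric(), y = numeric()))
  type <- feats[[1]]$geometry$type
  if (identical(type, "Point")) {
    rows <- lapply(feats, function(f) {
      c(list(x = f$geometry$coordinates[[1]], y = f$geometry$coordinates[[2]]),
        f$properties)
    })
    do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  } else {
    lapply(feats, function(f) {
      ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], unlist))
      ring[-nrow(ring), , drop = FALSE]
    })
  }
}
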