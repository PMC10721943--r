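#' Georeferenced grid raster
#'
#' A minimal single-band raster in a projected, metre-based coordinate
#' system: a numeric matrix plus origin and cell size. Row 1 is the
#' northernmost row; column 1 the westernmost column. Missing cells are `NA`.
#'
#' The package deliberately assumes a projected CRS in metres for every
#' layer, so all distance and area arithmetic is exact Euclidean geometry.
#' Geographic (degree) inputs are rejected, not reprojected.
#'
#' @param values numeric matrix of cell values (row 1 = north edge).
#' @param xmin,ymin coordinates (m) of the lower-left corner of the grid.
#' @param cellsize cell edge length in metres (> 0).
#' @param crs free-text tag for the projected CRS; `"local-metres"` default.
#' @return An object of class `grid_raster`.
#' @examples
#' r <- grid_raster(matrix(1:12, 3, 4), xmin = 0, ymin = 0, cellsize = 10)
#' dim(r$values)
#' raster_extent(r)
#' @export
grid_raster <- function(values, xmin = 0, ymin = 0, cellsize = 1,
                        crs = "local-metres") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (!is.finite(cellsize) || cellsize <= 0)
    stop("`cellsize` must be a positive length in metres", call. = FALSE)
  structure(
    list(values = values, xmin = xmin, ymin = ymin,
         cellsize = cellsize, crs = crs),
    class = "grid_raster"
  )
}

#' @export
print.grid_raster <- function(x, ...) {
  e <- raster_extent(x)
  cat(sprintf("<grid_raster> %d rows x %d cols @ %g m\n",
              nrow(x$values), ncol(x$values), x$cellsize))
  cat(sprintf("  extent: x [%g, %g], y [%g, %g] (%s)\n",
              e["xmin"], e["xmax"], e["ymin"], e["ymax"], x$crs))
  v <- x$values[is.finite(x$values)]
  if (length(v))
    cat(sprintf("  values: [%g, %g], %d NA cells\n", min(v), max(v),
                sum(!is.finite(x$values))))
  invisible(x)
}

#' Raster extent
#'
#' @param r a `grid_raster`.
#' @return Named numeric vector `xmin, xmax, ymin, ymax` (outer cell edges).
#' @export
raster_extent <- function(r) {
  c(xmin = r$xmin,
    xmax = r$xmin + ncol(r$values) * r$cellsize,
    ymin = r$ymin,
    ymax = r$ymin + nrow(r$values) * r$cellsize)
}

#' Cell-centre coordinates
#'
#' @param r a `grid_raster`.
#' @return A data.frame with `x`, `y`, `row`, `col`, `value` for every cell,
#'   in row-major order (north to south, west to east).
#' @export
cell_centers <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  ymax <- r$ymin + nr * r$cellsize
  cols <- rep(seq_len(nc), times = nr)
  rows <- rep(seq_len(nr), each = nc)
  data.frame(
    x = r$xmin + (cols - 0.5) * r$cellsize,
    y = ymax - (rows - 0.5) * r$cellsize,
    row = rows, col = cols,
    value = as.vector(t(r$values))
  )
}

# row/col of the cell containing each (x, y); NA outside the grid
cell_index <- function(r, x, y) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  ymax <- r$ymin + nr * r$cellsize
  col <- floor((x - r$xmin) / r$cellsize) + 1L
  row <- floor((ymax - y) / r$cellsize) + 1L
  # points exactly on the max edge belong to the last cell
  col[x == r$xmin + nc * r$cellsize] <- nc
  row[y == r$ymin] <- nr
  bad <- col < 1L | col > nc | row < 1L | row > nr
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  list(row = row, col = col)
}

#' Look up raster values at point locations
#'
#' Nearest-cell (containing cell) lookup. Points outside the raster return
#' `NA`.
#'
#' @param r a `grid_raster`.
#' @param x,y point coordinates in metres.
#' @return Numeric vector of cell values.
#' @export
raster_value_at <- function(r, x, y) {
  idx <- cell_index(r, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(idx$row)
  out[ok] <- r$values[cbind(idx$row[ok], idx$col[ok])]
  out
}

same_grid <- function(a, b, tol = 1e-9) {
  all(dim(a$values) == dim(b$values)) &&
    abs(a$xmin - b$xmin) < tol && abs(a$ymin - b$ymin) < tol &&
    abs(a$cellsize - b$cellsize) < tol
}

stopifnot_same_grid <- function(a, b, what = "rasters") {
  if (!same_grid(a, b))
    stop(sprintf("%s are not on the same grid (shape/origin/cell size)", what),
         call. = FALSE)
  invisible(TRUE)
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text interchange format readable by standard GIS tools. Values are
#' written row by row from the north edge; `NA` becomes the declared
#' `NODATA_value`.
#'
#' @param r a `grid_raster`.
#' @param path output file path (conventionally `.asc`).
#' @param nodata sentinel written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(r, path, nodata = -9999) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(r$values)),
    sprintf("nrows %d", nrow(r$values)),
    sprintf("xllcorner %.10g", r$xmin),
    sprintf("yllcorner %.10g", r$ymin),
    sprintf("cellsize %.10g", r$cellsize),
    sprintf("NODATA_value %g", nodata)
  ), con)
  vals <- r$values
  vals[!is.finite(vals)] <- nodata
  writeLines(apply(vals, 1L, function(row)
    paste(formatC(row, format = "g", digits = 10), collapse = " ")), con)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file written by [write_ascii_grid()] or any conforming tool.
#' @param crs CRS tag to attach.
#' @return A `grid_raster`.
#' @export
read_ascii_grid <- function(path, crs = "local-metres") {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  vals <- do.call(rbind, lapply(lines[i:length(lines)], function(l)
    as.numeric(strsplit(trimws(l), "[[:space:]]+")[[1]])))
  if (!is.null(hdr$nodata_value)) vals[vals == hdr$nodata_value] <- NA_real_
  grid_raster(vals, xmin = hdr$xllcorner, ymin = hdr$yllcorner,
              cellsize = hdr$cellsize, crs = crs)
}

# master seed -> named substream seed (stable, < 2^31)
substream_seed <- function(seed, stream) {
  offs <- c(dem = 11L, geology = 23L, bands = 37L, species = 53L,
            survey = 71L, background = 89L, split = 101L, model = 127L)
  o <- offs[[stream]]
  if (is.null(o)) stop("unknown substream: ", stream, call. = FALSE)
  as.integer((as.numeric(seed) * 181L + o * 7919) %% 2147483647)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}
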