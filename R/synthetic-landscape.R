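#' Configuration for a synthetic landscape
#'
#' Describes the simulated study system: a rectangular, projected-metres
#' landscape with fine-grained terrain (1-m cells by default, emulating a
#' LiDAR-derived DEM), a coarse precipitation gradient (800-m cells by
#' default, emulating gridded climate normals), and a single target geologic
#' formation occupying a minority of the extent. Every downstream stage of
#' the pipeline can be exercised against this landscape because the habitat
#' truth is known by construction.
#'
#' @param width_m,height_m extent dimensions in metres; must be positive
#'   integer multiples of `cell_size_m`.
#' @param cell_size_m fine-grid cell size in metres (default 1).
#' @param precip_cell_size_m coarse precipitation cell size (default 800);
#'   must be at least `cell_size_m`.
#' @param relief_amplitude_m total elevation range of the generated DEM (m).
#' @param roughness positive scalar controlling terrain texture: larger
#'   values mean shorter-range spatial autocorrelation (rougher terrain).
#' @param formation_fraction target fraction of the extent occupied by the
#'   focal geologic formation, in (0, 1).
#' @param xmin,ymin lower-left corner of the extent.
#' @param seed master integer seed; each generator draws from a named
#'   substream derived from it, so stages are independently reproducible.
#' @return A `landscape_config` list.
#' @export
landscape_config <- function(width_m = 300, height_m = 300, cell_size_m = 1,
                             precip_cell_size_m = 800,
                             relief_amplitude_m = 30, roughness = 0.1,
                             formation_fraction = 0.3,
                             xmin = 0, ymin = 0, seed = 1L) {
  if (width_m <= 0 || height_m <= 0 || cell_size_m <= 0)
    stop("extent dimensions and cell size must be positive", call. = FALSE)
  if (abs(width_m / cell_size_m - round(width_m / cell_size_m)) > 1e-9 ||
      abs(height_m / cell_size_m - round(height_m / cell_size_m)) > 1e-9)
    stop("extent must be an integer multiple of the cell size", call. = FALSE)
  if (precip_cell_size_m < cell_size_m)
    stop("precip_cell_size_m must be >= cell_size_m", call. = FALSE)
  if (formation_fraction <= 0 || formation_fraction >= 1)
    stop("formation_fraction must lie in (0, 1)", call. = FALSE)
  if (relief_amplitude_m < 0 || roughness < 0)
    stop("relief_amplitude_m and roughness must be non-negative",
         call. = FALSE)
  structure(
    list(width_m = width_m, height_m = height_m, cell_size_m = cell_size_m,
         precip_cell_size_m = precip_cell_size_m,
         relief_amplitude_m = relief_amplitude_m, roughness = roughness,
         formation_fraction = formation_fraction,
         xmin = xmin, ymin = ymin, seed = as.integer(seed)),
    class = "landscape_config"
  )
}

# separable Gaussian smoothing with edge replication
gaussian_smooth_matrix <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  pad_idx <- function(n) c(rep(1L, half), seq_len(n), rep(n, half))
  smooth_rows <- function(mm) {
    padded <- mm[, pad_idx(ncol(mm)), drop = FALSE]
    out <- matrix(0, nrow(mm), ncol(mm))
    for (j in seq_along(k))
      out <- out + k[j] * padded[, j:(j + ncol(mm) - 1L), drop = FALSE]
    out
  }
  t(smooth_rows(t(smooth_rows(m))))
}

#' Generate a synthetic digital elevation model
#'
#' A smoothed Gaussian random field: white noise low-pass filtered with a
#' Gaussian kernel whose bandwidth is the reciprocal of
#' `config$roughness` (in cells), then rescaled so the elevation range
#' equals `config$relief_amplitude_m`. With zero amplitude the DEM is
#' perfectly flat. Deterministic for a fixed config seed.
#'
#' @param config a [landscape_config()].
#' @return A `grid_raster` of elevations (m).
#' @export
generate_dem <- function(config) {
  nr <- as.integer(round(config$height_m / config$cell_size_m))
  nc <- as.integer(round(config$width_m / config$cell_size_m))
  vals <- with_seed(substream_seed(config$seed, "dem"), {
    field <- matrix(stats::rnorm(nr * nc), nr, nc)
    sigma <- if (config$roughness > 0) 1 / config$roughness else 0
    field <- gaussian_smooth_matrix(field, sigma)
    rng <- diff(range(field))
    if (config$relief_amplitude_m == 0 || rng == 0) {
      matrix(0, nr, nc)
    } else {
      (field - min(field)) / rng * config$relief_amplitude_m
    }
  })
  grid_raster(vals, xmin = config$xmin, ymin = config$ymin,
              cellsize = config$cell_size_m)
}

# star-shaped blob polygon: radius varies smoothly around the perimeter
blob_polygon <- function(cx, cy, mean_radius, irregularity = 0.4,
                         n_vertices = 28L) {
  ang <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  raw <- stats::rnorm(n_vertices)
  # periodic smoothing of the radial noise so the outline is not jagged
  sm <- stats::filter(rep(raw, 3), rep(1 / 5, 5), circular = TRUE)
  sm <- sm[(n_vertices + 1L):(2L * n_vertices)]
  radius <- mean_radius * exp(irregularity * as.numeric(sm))
  cbind(cx + radius * cos(ang), cy + radius * sin(ang))
}

#' Generate a synthetic geologic formation
#'
#' Grows irregular "badland" blobs (star-shaped polygons with smoothly
#' varying radius) at random centres until the fraction of fine-grid cell
#' centres falling inside the formation reaches the configured
#' `formation_fraction`. The polygon set and the raster mask are consistent
#' by construction: the mask is 1 exactly where a cell centre lies inside
#' at least one polygon.
#'
#' @param config a [landscape_config()].
#' @return A list with `polygons` (list of vertex matrices) and `mask`
#'   (a 0/1 `grid_raster`).
#' @export
generate_geology <- function(config) {
  nr <- as.integer(round(config$height_m / config$cell_size_m))
  nc <- as.integer(round(config$width_m / config$cell_size_m))
  template <- grid_raster(matrix(0, nr, nc), xmin = config$xmin,
                          ymin = config$ymin, cellsize = config$cell_size_m)
  cc <- cell_centers(template)
  target <- config$formation_fraction
  total_area <- config$width_m * config$height_m
  # aim for ~6 blobs; each adds at most ~target/6 so overshoot stays < +20%
  mean_radius <- sqrt(target * total_area / 6 / pi)
  res <- with_seed(substream_seed(config$seed, "geology"), {
    polys <- list()
    inside <- rep(FALSE, nrow(cc))
    for (i in seq_len(60L)) {
      if (mean(inside) >= target) break
      cx <- stats::runif(1, config$xmin + mean_radius,
                         config$xmin + config$width_m - mean_radius)
      cy <- stats::runif(1, config$ymin + mean_radius,
                         config$ymin + config$height_m - mean_radius)
      p <- blob_polygon(cx, cy, mean_radius)
      p[, 1] <- pmin(pmax(p[, 1], config$xmin), config$xmin + config$width_m)
      p[, 2] <- pmin(pmax(p[, 2], config$ymin), config$ymin + config$height_m)
      polys[[length(polys) + 1L]] <- p
      todo <- which(!inside)
      inside[todo] <- mgcv::in.out(rbind(p, p[1, ]),
                                   cbind(cc$x[todo], cc$y[todo]))
    }
    list(polys = polys, inside = inside)
  })
  mask_vals <- matrix(0, nr, nc)
  mask_vals[cbind(cc$row, cc$col)] <- as.numeric(res$inside)
  list(polygons = res$polys,
       mask = grid_raster(mask_vals, xmin = config$xmin, ymin = config$ymin,
                          cellsize = config$cell_size_m))
}

#' Generate a coarse precipitation gradient
#'
#' A coarse raster (cell size `config$precip_cell_size_m`) whose values run
#' linearly from `low` on the northernmost row of cell centres to `high` on
#' the southernmost, emulating the study system's north-to-south annual
#' precipitation gradient. Units are whatever `low`/`high` are given in
#' (millimetres throughout this package).
#'
#' @param config a [landscape_config()].
#' @param low,high precipitation at the north and south edges; `low < high`.
#' @return A coarse `grid_raster` covering the configured extent.
#' @export
generate_precipitation <- function(config, low = 220, high = 320) {
  if (low >= high) stop("`low` must be strictly less than `high`",
                        call. = FALSE)
  cs <- config$precip_cell_size_m
  nc <- max(1L, ceiling(config$width_m / cs))
  nr <- max(1L, ceiling(config$height_m / cs))
  if (nr == 1L) {
    vals <- matrix((low + high) / 2, 1L, nc)
  } else {
    vals <- matrix(seq(low, high, length.out = nr), nr, nc)
  }
  grid_raster(vals, xmin = config$xmin, ymin = config$ymin, cellsize = cs)
}

#' Generate synthetic red and green reflectance bands
#'
#' Reflectance is a two-level surface (one mean on the formation, another
#' off it) plus Gaussian noise, built so the soil colour index
#' `(R - G)/(R + G)` is elevated on-formation. Deterministic per seed.
#'
#' @param mask 0/1 formation `grid_raster` from [generate_geology()].
#' @param on_red,on_green mean reflectances on the formation.
#' @param off_red,off_green mean reflectances off the formation.
#' @param noise_sd standard deviation of the additive noise (>= 0).
#' @param seed integer seed.
#' @return A list with `red` and `green` `grid_raster`s.
#' @export
generate_spectral_bands <- function(mask, on_red = 0.30, on_green = 0.20,
                                    off_red = 0.22, off_green = 0.22,
                                    noise_sd = 0.02, seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  on <- mask$values > 0
  red <- ifelse(on, on_red, off_red)
  green <- ifelse(on, on_green, off_green)
  dims <- dim(mask$values)
  if (noise_sd > 0) {
    noise <- with_seed(substream_seed(seed, "bands"), {
      list(r = matrix(stats::rnorm(prod(dims), sd = noise_sd), dims[1], dims[2]),
           g = matrix(stats::rnorm(prod(dims), sd = noise_sd), dims[1], dims[2]))
    })
    red <- red + noise$r
    green <- green + noise$g
  }
  red <- pmax(red, 0); green <- pmax(green, 0)
  list(red = grid_raster(matrix(red, dims[1], dims[2]), mask$xmin, mask$ymin,
                         mask$cellsize),
       green = grid_raster(matrix(green, dims[1], dims[2]), mask$xmin,
                           mask$ymin, mask$cellsize))
}

#' Define a logistic habitat-suitability truth
#'
#' Builds a "virtual species": true suitability is the inverse logit of a
#' linear combination of standardized covariate layers. Standardization
#' (z-scoring each layer over its finite cells) makes the coefficients
#' directly interpretable as effect sizes. Used to generate occurrences and
#' to score how well the fitted models recover a known habitat function.
#'
#' @param layers named list of aligned `grid_raster` covariate layers.
#' @param coefficients named numeric vector; names must match `layers`.
#' @param intercept scalar intercept on the logit scale.
#' @return A `truth_model` list: `coefficients`, `intercept`,
#'   `suitability` (a `grid_raster` of probabilities), `standardization`.
#' @export
define_true_suitability <- function(layers, coefficients, intercept = 0) {
  missing_layers <- setdiff(names(coefficients), names(layers))
  if (length(missing_layers))
    stop("no covariate layer for coefficient(s): ",
         paste(missing_layers, collapse = ", "), call. = FALSE)
  base <- layers[[1]]
  lin <- matrix(intercept, nrow(base$values), ncol(base$values))
  standardization <- list()
  for (nm in names(coefficients)) {
    stopifnot_same_grid(base, layers[[nm]], "covariate layers")
    v <- layers[[nm]]$values
    mu <- mean(v[is.finite(v)])
    sdv <- stats::sd(v[is.finite(v)])
    if (!is.finite(sdv) || sdv == 0) sdv <- 1
    standardization[[nm]] <- c(mean = mu, sd = sdv)
    lin <- lin + coefficients[[nm]] * (v - mu) / sdv
  }
  structure(
    list(coefficients = coefficients, intercept = intercept,
         suitability = grid_raster(stats::plogis(lin), base$xmin, base$ymin,
                                   base$cellsize),
         standardization = standardization),
    class = "truth_model"
  )
}

#' Sample occurrences of the virtual species
#'
#' Presence points are drawn cell-by-cell with probability proportional to
#' true suitability, then jittered uniformly within their cell. Subpopulation
#' polygons — emulating field-mapped patches of locally continuous
#' occupancy — are irregular blobs centred on cells sampled with weight
#' proportional to the cube of suitability (concentrating them in strongly
#' suitable terrain).
#'
#' @param truth a `truth_model` from [define_true_suitability()].
#' @param n_points number of presence points to draw.
#' @param n_polygons number of subpopulation polygons.
#' @param polygon_radius_m mean radius of subpopulation blobs (m).
#' @param seed integer seed.
#' @return A list with `points` (data.frame `x`, `y`) and `polygons`
#'   (list of vertex matrices), both inside the landscape extent.
#' @export
sample_virtual_species <- function(truth, n_points, n_polygons = 0L,
                                   polygon_radius_m = 30, seed = 1L) {
  if (!inherits(truth, "truth_model"))
    stop("`truth` must be a truth_model (see define_true_suitability)",
         call. = FALSE)
  if (n_points < 0 || n_polygons < 0)
    stop("n_points and n_polygons must be >= 0", call. = FALSE)
  r <- truth$suitability
  cc <- cell_centers(r)
  w <- cc$value
  w[!is.finite(w)] <- 0
  ext <- raster_extent(r)
  with_seed(substream_seed(seed, "species"), {
    pts <- if (n_points > 0 && sum(w) > 0) {
      idx <- sample.int(nrow(cc), n_points, replace = TRUE, prob = w)
      data.frame(
        x = cc$x[idx] + stats::runif(n_points, -0.5, 0.5) * r$cellsize,
        y = cc$y[idx] + stats::runif(n_points, -0.5, 0.5) * r$cellsize
      )
    } else data.frame(x = numeric(), y = numeric())
    polys <- list()
    if (n_polygons > 0 && sum(w^3) > 0) {
      ctr <- sample.int(nrow(cc), n_polygons, replace = FALSE, prob = w^3)
      for (i in seq_len(n_polygons)) {
        p <- blob_polygon(cc$x[ctr[i]], cc$y[ctr[i]], polygon_radius_m,
                          irregularity = 0.3)
        p[, 1] <- pmin(pmax(p[, 1], ext["xmin"]), ext["xmax"])
        p[, 2] <- pmin(pmax(p[, 2], ext["ymin"]), ext["ymax"])
        polys[[i]] <- p
      }
    }
    list(points = pts, polygons = polys)
  })
}

#' Generate survey cells with detections
#'
#' Places `n_cells` non-overlapping square cells on a grid aligned to the
#' suitability raster (default 50-m cells), computes each cell's mean true
#' suitability, and draws a detection flag from `detection_rule`. Cell
#' placement is a configurable policy: `"random"` draws cells uniformly;
#' `"weighted"` favours cells with high mean suitability (emulating surveys
#' that target predicted habitat).
#'
#' @param suitability a `grid_raster` of true (or predicted) suitability.
#' @param n_cells number of cells to place (>= 1).
#' @param cell_size_m survey cell edge length; must be an integer multiple
#'   of the raster cell size.
#' @param detection_rule function mapping mean suitability to detection
#'   probability. Default: identity clipped to [0.01, 0.99], which keeps
#'   both detected and undetected cells represented.
#' @param placement `"random"` or `"weighted"`.
#' @param seed integer seed.
#' @return A `survey_cells` data.frame: `cell_id`, `x_min`, `y_min`,
#'   `detected` (0/1), `truth_mean`.
#' @export
generate_survey_cells <- function(suitability, n_cells, cell_size_m = 50,
                                  detection_rule = NULL,
                                  placement = c("random", "weighted"),
                                  seed = 1L) {
  placement <- match.arg(placement)
  if (n_cells < 1) stop("n_cells must be >= 1", call. = FALSE)
  ratio <- cell_size_m / suitability$cellsize
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("survey cell size must be an integer multiple of the raster cell size",
         call. = FALSE)
  if (is.null(detection_rule))
    detection_rule <- function(p) pmin(pmax(p, 0.01), 0.99)
  k <- as.integer(round(ratio))
  nr <- nrow(suitability$values) %/% k
  nc <- ncol(suitability$values) %/% k
  if (nr * nc < n_cells)
    stop("extent holds only ", nr * nc, " survey cells; ", n_cells,
         " requested", call. = FALSE)
  # mean suitability per candidate cell via block aggregation
  sub <- suitability$values[seq_len(nr * k), seq_len(nc * k), drop = FALSE]
  blocks <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    blk <- sub[((i - 1L) * k + 1L):(i * k), ((j - 1L) * k + 1L):(j * k)]
    blocks[i, j] <- mean(blk[is.finite(blk)])
  }
  ymax <- suitability$ymin + nrow(suitability$values) * suitability$cellsize
  with_seed(substream_seed(seed, "survey"), {
    wts <- if (placement == "weighted") {
      pmax(as.vector(blocks), 1e-6)
    } else rep(1, nr * nc)
    wts[!is.finite(as.vector(blocks))] <- 0
    pick <- sample.int(nr * nc, n_cells, replace = FALSE, prob = wts)
    bi <- (pick - 1L) %% nr + 1L     # block row (from north)
    bj <- (pick - 1L) %/% nr + 1L    # block col
    truth_mean <- blocks[cbind(bi, bj)]
    p_detect <- detection_rule(truth_mean)
    data.frame(
      cell_id = seq_len(n_cells),
      x_min = suitability$xmin + (bj - 1L) * cell_size_m,
      y_min = ymax - bi * cell_size_m,
      detected = as.integer(stats::runif(n_cells) < p_detect),
      truth_mean = truth_mean
    )
  })
}
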