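#' AUC-PR-proportional ensemble weights
#'
#' Each included model's weight is its AUC-PR divided by the sum of the
#' included models' AUC-PRs, so weights are non-negative and sum to one.
#' Models outside the include list (e.g. a model whose AUC-PR lags the
#' rest) receive no weight.
#'
#' @param auc_pr named numeric vector of per-model AUC-PR values.
#' @param include character vector of model ids to include (default: all).
#' @return Named numeric vector of weights summing to 1.
#' @export
ensemble_weights <- function(auc_pr, include = names(auc_pr)) {
  if (!length(include)) stop("include list is empty", call. = FALSE)
  missing_ids <- setdiff(include, names(auc_pr))
  if (length(missing_ids))
    stop("no AUC-PR for model(s): ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  v <- auc_pr[include]
  if (any(v <= 0)) stop("included AUC-PR values must be > 0", call. = FALSE)
  v / sum(v)
}

#' Weighted ensemble prediction
#'
#' Convex combination of member predictions: each member is multiplied by
#' its weight and the results are summed, pointwise or cellwise. The
#' ensemble therefore always lies within the member predictions' range.
#'
#' @param predictions named list of numeric vectors (point scores) or
#'   `grid_raster`s, one per model; names must cover `names(weights)`.
#' @param weights weights from [ensemble_weights()].
#' @return A numeric vector or `grid_raster` matching the inputs.
#' @export
ensemble_predict <- function(predictions, weights) {
  ids <- names(weights)
  missing_ids <- setdiff(ids, names(predictions))
  if (length(missing_ids))
    stop("no predictions for model(s): ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  first <- predictions[[ids[1]]]
  if (inherits(first, "grid_raster")) {
    acc <- first$values * weights[[ids[1]]]
    for (id in ids[-1]) {
      stopifnot_same_grid(first, predictions[[id]], "member rasters")
      acc <- acc + predictions[[id]]$values * weights[[id]]
    }
    grid_raster(acc, first$xmin, first$ymin, first$cellsize)
  } else {
    acc <- first * weights[[ids[1]]]
    for (id in ids[-1]) {
      if (length(predictions[[id]]) != length(first))
        stop("member prediction lengths differ", call. = FALSE)
      acc <- acc + predictions[[id]] * weights[[id]]
    }
    acc
  }
}

#' Fixed-sensitivity suitability threshold
#'
#' Finds the highest cutoff that still classifies at least a target
#' fraction (default 95%) of known presences as suitable. For a rare
#' species the cost of calling true habitat unsuitable far exceeds the
#' cost of the reverse error, so the threshold is anchored on sensitivity
#' rather than on overall accuracy. Candidate cutoffs are the observed
#' presence scores together with 0 and 1; classification is
#' `score >= threshold` (ties suitable).
#'
#' @param presence_scores suitability scores at known presences.
#' @param target target sensitivity in (0, 1] (default 0.95).
#' @return A `threshold_result` list: `threshold`, `target_sensitivity`,
#'   `achieved_sensitivity`.
#' @export
fixed_sensitivity_threshold <- function(presence_scores, target = 0.95) {
  if (!length(presence_scores)) stop("no presence scores", call. = FALSE)
  if (length(presence_scores) < 20)
    warning("fewer than 20 presence scores; threshold is unstable",
            call. = FALSE)
  cand <- sort(unique(c(0, 1, presence_scores)), decreasing = TRUE)
  n <- length(presence_scores)
  for (t in cand) {
    sens <- sum(presence_scores >= t) / n
    if (sens >= target) {
      return(structure(list(threshold = t, target_sensitivity = target,
                            achieved_sensitivity = sens),
                       class = "threshold_result"))
    }
  }
  # target <= 0 degenerates to the largest candidate
  structure(list(threshold = cand[1], target_sensitivity = target,
                 achieved_sensitivity = 1),
            class = "threshold_result")
}

KM2_TO_ACRES <- 247.10538

#' Classify a suitability raster and account for suitable area
#'
#' Applies a cutoff to a suitability raster (`>= t` is suitable), reports
#' the suitable fraction of valid cells and the suitable area in km^2 and
#' acres (1 km^2 = 247.10538 acres; acres rounded to the nearest integer
#' for reporting). If labelled point scores are supplied, sensitivity and
#' specificity at the cutoff are reported as well.
#'
#' @param raster a `grid_raster` of suitability scores.
#' @param threshold cutoff in [0, 1].
#' @param scores,labels optional point scores and 0/1 labels for
#'   sensitivity/specificity at the cutoff.
#' @return A `threshold_result` list: `threshold`, `suitable_fraction`,
#'   `suitable_km2`, `suitable_acres`, `binary` (0/1 `grid_raster`), and,
#'   when labels are given, `sensitivity` and `specificity`.
#' @export
classify_and_account <- function(raster, threshold, scores = NULL,
                                 labels = NULL) {
  v <- raster$values
  valid <- is.finite(v)
  if (!any(valid)) stop("raster has no valid cells", call. = FALSE)
  suitable <- valid & v >= threshold
  frac <- sum(suitable) / sum(valid)
  km2 <- sum(suitable) * raster$cellsize^2 / 1e6
  out <- list(threshold = threshold,
              suitable_fraction = frac,
              suitable_km2 = km2,
              suitable_acres = round(km2 * KM2_TO_ACRES),
              binary = grid_raster(matrix(as.numeric(suitable), nrow(v),
                                          ncol(v)),
                                   raster$xmin, raster$ymin,
                                   raster$cellsize))
  if (!is.null(scores) && !is.null(labels)) {
    labels <- as.integer(as.logical(labels))
    out$sensitivity <- mean(scores[labels == 1] >= threshold)
    out$specificity <- mean(scores[labels == 0] < threshold)
  }
  structure(out, class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result> t = %.4g", x$threshold))
  if (!is.null(x$achieved_sensitivity))
    cat(sprintf(" (target sens %.3g, achieved %.3g)",
                x$target_sensitivity, x$achieved_sensitivity))
  cat("\n")
  if (!is.null(x$suitable_fraction))
    cat(sprintf("  suitable: %.2f%% of valid cells, %.4g km2 (%d acres)\n",
                100 * x$suitable_fraction, x$suitable_km2,
                x$suitable_acres))
  if (!is.null(x$sensitivity))
    cat(sprintf("  at points: sensitivity %.3f, specificity %.3f\n",
                x$sensitivity, x$specificity))
  invisible(x)
}
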