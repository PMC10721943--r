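#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney probability that a random positive
#' outscores a random negative, with ties counted half (midrank
#' correction). Threshold-independent and invariant to monotone
#' transformations of the scores.
#'
#' @param scores numeric suitability scores.
#' @param labels 0/1 (or logical) class labels; 1 = presence.
#' @return Scalar AUC-ROC in [0, 1].
#' @export
auc_roc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present", call. = FALSE)
  r <- rank(scores)          # midranks
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' The average-precision estimator: walking down the score ranking, each
#' positive contributes the precision at its rank, and the mean over
#' positives is returned. Tied scores are treated as one block whose
#' positives all receive the precision at the block's end, so the result
#' does not depend on the arbitrary order within ties. Preferred over
#' trapezoidal interpolation in precision-recall space, which is
#' optimistic. For a random ranking the value approaches the prevalence of
#' positives — the natural baseline for rare-species data.
#'
#' @param scores numeric suitability scores.
#' @param labels 0/1 class labels; at least one positive required.
#' @return Scalar AUC-PR in (0, 1].
#' @export
auc_pr <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (!any(labels == 1)) stop("no positive labels", call. = FALSE)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  block <- cumsum(!duplicated(s))              # tie-block id, descending
  n_in <- tapply(rep(1L, length(s)), block, sum)
  pos_in <- tapply(l, block, sum)
  cum_n <- cumsum(n_in)
  cum_pos <- cumsum(pos_in)
  sum(pos_in * (cum_pos / cum_n)) / sum(l)
}

#' Pearson correlation between scores and labels
#'
#' The product-moment correlation of predicted suitability against the
#' 0/1 occurrence indicator (the point-biserial correlation). Unlike the
#' rank-based AUC metrics it is sensitive to calibration of the score
#' values themselves.
#'
#' @param scores numeric suitability scores.
#' @param labels 0/1 class labels.
#' @return Scalar correlation in [-1, 1].
#' @export
pearson_correlation <- function(scores, labels) {
  labels <- as.numeric(as.logical(labels))
  if (stats::sd(scores) == 0 || stats::sd(labels) == 0)
    stop("zero variance in scores or labels", call. = FALSE)
  stats::cor(scores, labels)
}

#' Per-model validation metrics
#'
#' Convenience wrapper computing all three threshold-independent metrics
#' for one score vector.
#'
#' @param model_id identifier string.
#' @param scores,labels as in [auc_roc()].
#' @return One-row data.frame: `model_id`, `auc_roc`, `auc_pr`,
#'   `pearson_r`.
#' @export
metric_row <- function(model_id, scores, labels) {
  data.frame(model_id = model_id,
             auc_roc = auc_roc(scores, labels),
             auc_pr = auc_pr(scores, labels),
             pearson_r = pearson_correlation(scores, labels))
}

#' Normalized average of validation metrics
#'
#' Ranks models across metrics with different scales by min-max scaling
#' each metric column to [0, 1] across all supplied rows — including any
#' ensemble row — and averaging the three scaled values per model. The
#' best model in a metric scales to 1, the worst to 0; a metric with zero
#' range is uninformative and contributes 0.5 to every model.
#'
#' @param metrics data.frame with columns `model_id`, `auc_roc`,
#'   `auc_pr`, `pearson_r` (>= 2 rows).
#' @return The input with `scaled_auc_roc`, `scaled_auc_pr`, `scaled_r`
#'   and `average` columns appended.
#' @export
normalized_average <- function(metrics) {
  if (nrow(metrics) < 2)
    stop("need at least 2 model rows to scale", call. = FALSE)
  scale01 <- function(v) {
    rng <- range(v)
    if (diff(rng) == 0) return(rep(0.5, length(v)))
    (v - rng[1]) / diff(rng)
  }
  metrics$scaled_auc_roc <- scale01(metrics$auc_roc)
  metrics$scaled_auc_pr <- scale01(metrics$auc_pr)
  metrics$scaled_r <- scale01(metrics$pearson_r)
  metrics$average <- (metrics$scaled_auc_roc + metrics$scaled_auc_pr +
                        metrics$scaled_r) / 3
  metrics
}

#' Published reference metric tables
#'
#' The per-model validation metrics reported by the field-validated
#' ensemble habitat-suitability study whose workflow this package's
#' `original` and `final` presets mirror. Shipped so the normalized
#' average and ensemble-weight arithmetic can be reproduced exactly from
#' the printed values.
#'
#' @return A list of two data.frames (`original`, `final`) with columns
#'   `model_id`, `auc_roc`, `auc_pr`, `pearson_r`.
#' @export
reference_metric_tables <- function() {
  list(
    original = data.frame(
      model_id = c("rf_downsampled", "rf_shallow", "brt", "maxent",
                   "ensemble"),
      auc_roc = c(0.989, 0.987, 0.989, 0.980, 0.989),
      auc_pr = c(0.792, 0.773, 0.728, 0.618, 0.793),
      pearson_r = c(0.606, 0.547, 0.623, 0.608, 0.599)
    ),
    final = data.frame(
      model_id = c("rf_downsampled", "brt", "maxent", "mars", "gam",
                   "ensemble"),
      auc_roc = c(0.991, 0.992, 0.980, 0.967, 0.960, 0.990),
      auc_pr = c(0.845, 0.844, 0.727, 0.684, 0.347, 0.825),
      pearson_r = c(0.619, 0.682, 0.679, 0.654, 0.392, 0.663)
    )
  )
}
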