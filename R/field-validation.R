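#' Ensemble suitability of survey cells
#'
#' Summarizes a fine-resolution suitability raster within each square
#' survey cell as the mean of the valid prediction cells whose centres
#' fall inside the cell. Cells containing no valid prediction data are
#' excluded and reported.
#'
#' @param raster a `grid_raster` of (ensemble) suitability.
#' @param cells a `survey_cells` data.frame (`cell_id`, `x_min`, `y_min`,
#'   `detected`, ...).
#' @param cell_size_m survey cell edge length (default 50).
#' @param statistic `"mean"` (default), `"max"` or `"center"`.
#' @return The input cells with a `suitability` column, minus excluded
#'   cells; excluded cell ids are in attribute `"excluded"`.
#' @export
cell_suitability <- function(raster, cells, cell_size_m = 50,
                             statistic = c("mean", "max", "center")) {
  statistic <- match.arg(statistic)
  cc <- cell_centers(raster)
  suit <- rep(NA_real_, nrow(cells))
  for (i in seq_len(nrow(cells))) {
    x0 <- cells$x_min[i]; y0 <- cells$y_min[i]
    if (statistic == "center") {
      suit[i] <- raster_value_at(raster, x0 + cell_size_m / 2,
                                 y0 + cell_size_m / 2)
      next
    }
    inside <- cc$x > x0 & cc$x < x0 + cell_size_m &
      cc$y > y0 & cc$y < y0 + cell_size_m
    v <- cc$value[inside]
    v <- v[is.finite(v)]
    if (length(v))
      suit[i] <- if (statistic == "mean") mean(v) else max(v)
  }
  ok <- is.finite(suit)
  out <- cells[ok, , drop = FALSE]
  out$suitability <- suit[ok]
  attr(out, "excluded") <- cells$cell_id[!ok]
  out
}

#' Cliff's delta effect size
#'
#' The nonparametric dominance statistic
#' `d = P(x > y) - P(x < y)` over all cross-group pairs, in [-1, 1];
#' |d| above roughly 0.147/0.33/0.474 is conventionally small/medium/
#' large. Computed exactly through midranks, which is algebraically
#' identical to all-pairs enumeration but O(n log n).
#'
#' @param x,y numeric samples (both non-empty).
#' @return Scalar delta in [-1, 1].
#' @export
cliffs_delta <- function(x, y) {
  if (!length(x) || !length(y))
    stop("both groups must be non-empty", call. = FALSE)
  r <- rank(c(x, y))
  nx <- length(x); ny <- length(y)
  # U = #(x > y) + 0.5 #(x == y), via the rank-sum identity
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  2 * u / (nx * ny) - 1
}

#' One-sided Wilcoxon rank-sum test
#'
#' Tests whether `x` is stochastically greater than `y` using the
#' rank-sum statistic with midranks for ties. Small untied samples get
#' the exact null distribution; otherwise the normal approximation with
#' tie correction and continuity correction is used (the behaviour of
#' [stats::wilcox.test()], which performs the computation).
#'
#' @param x,y numeric samples (both non-empty).
#' @return A list with `statistic` (the Mann-Whitney U of `x` over `y`)
#'   and `p_value`.
#' @export
wilcoxon_rank_sum_one_sided <- function(x, y) {
  if (!length(x) || !length(y))
    stop("both groups must be non-empty", call. = FALSE)
  wt <- stats::wilcox.test(x, y, alternative = "greater")
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Thresholded contingency analysis of survey cells
#'
#' Splits survey cells into predicted-suitable (`suitability >= t`) and
#' predicted-unsuitable, crosses that with the detection flag, and tests
#' association with a Pearson chi-square (no continuity correction).
#' Cramer's V, which for a 2x2 table reduces to `sqrt(chi2 / n)`, is
#' reported as the effect size, along with the detection percentage in
#' each predicted class.
#'
#' @param cells a `survey_cells` data.frame with `suitability` and
#'   `detected` columns.
#' @param threshold suitability cutoff.
#' @return A list: `table` (2x2 counts, suitable x detected),
#'   `chi_square`, `p_value`, `cramers_v`, `pct_detected_suitable`,
#'   `pct_detected_unsuitable`.
#' @export
threshold_contingency <- function(cells, threshold) {
  suitable <- factor(cells$suitability >= threshold,
                     levels = c(TRUE, FALSE),
                     labels = c("suitable", "unsuitable"))
  detected <- factor(cells$detected == 1, levels = c(TRUE, FALSE),
                     labels = c("detected", "not_detected"))
  tab <- table(suitable, detected)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("a margin of the contingency table is zero; ",
         "both threshold classes and both detection classes are required",
         call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  n <- sum(tab)
  out <- list(table = tab,
              chi_square = unname(ct$statistic),
              p_value = ct$p.value,
              cramers_v = sqrt(unname(ct$statistic) / n))
  # the chi-square approximation is poor with sparse expected counts;
  # offer Fisher's exact p alongside in that regime
  if (any(ct$expected < 5))
    out$fisher_p <- stats::fisher.test(tab)$p.value
  c(out, list(
    pct_detected_suitable = 100 * tab["suitable", "detected"] /
      sum(tab["suitable", ]),
    pct_detected_unsuitable = 100 * tab["unsuitable", "detected"] /
      sum(tab["unsuitable", ])))
}

#' Field-survey summary and validation statistics
#'
#' The headline comparison of the field validation: ensemble suitability
#' in detected versus undetected cells (group means and SDs), the
#' one-sided rank-sum test that detected cells score higher, and Cliff's
#' delta. Undetected surveyed cells are treated as true absences;
#' imperfect detection is not modelled. Total surveyed area assumes
#' square cells of `cell_size_m`.
#'
#' @param cells a `survey_cells` data.frame with `suitability` and
#'   `detected` columns.
#' @param cell_size_m survey cell edge length (default 50).
#' @return A `field_validation_result` list.
#' @export
summarize_survey <- function(cells, cell_size_m = 50) {
  km2 <- nrow(cells) * cell_size_m^2 / 1e6
  det <- cells$suitability[cells$detected == 1]
  und <- cells$suitability[cells$detected == 0]
  res <- list(
    n_cells = nrow(cells),
    n_detected = length(det),
    n_undetected = length(und),
    surveyed_km2 = km2,
    surveyed_acres = km2 * KM2_TO_ACRES,
    mean_detected = if (length(det)) mean(det) else NA_real_,
    sd_detected = if (length(det) > 1) stats::sd(det) else NA_real_,
    mean_undetected = if (length(und)) mean(und) else NA_real_,
    sd_undetected = if (length(und) > 1) stats::sd(und) else NA_real_
  )
  if (length(det) && length(und)) {
    w <- wilcoxon_rank_sum_one_sided(det, und)
    res$wilcoxon_statistic <- w$statistic
    res$wilcoxon_p <- w$p_value
    res$cliffs_delta <- cliffs_delta(det, und)
  }
  structure(res, class = "field_validation_result")
}

#' @export
print.field_validation_result <- function(x, ...) {
  cat(sprintf("<field_validation> %d cells (%.3g km2, %.1f acres)\n",
              x$n_cells, x$surveyed_km2, x$surveyed_acres))
  cat(sprintf("  detected %d | undetected %d\n", x$n_detected,
              x$n_undetected))
  if (!is.null(x$cliffs_delta)) {
    cat(sprintf("  suitability: detected %.3f (SD %.3f) vs undetected %.3f (SD %.3f)\n",
                x$mean_detected, x$sd_detected, x$mean_undetected,
                x$sd_undetected))
    cat(sprintf("  one-sided rank-sum p = %.3g, Cliff's delta = %.3f\n",
                x$wilcoxon_p, x$cliffs_delta))
  }
  invisible(x)
}
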