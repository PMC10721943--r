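#' Workflow configuration
#'
#' Bundles every tunable of the end-to-end pipeline under the two study
#' presets. The `original` preset models terrain + precipitation + geology
#' covariates with downsampled RF, shallow RF, BRT and the regularized
#' presence-background logistic model ("maxent"), and leaves the latter out
#' of the ensemble. The `final` preset adds the soil colour index
#' covariate and true-absence points from surveyed cells, swaps the
#' shallow RF for MARS and GAM, applies the stricter point-engineering
#' rules (2-m presence thinning, 40-m polygon-point thinning, 100-m
#' background/absence exclusion) and includes every model in the ensemble.
#'
#' Every distance and fraction of the point-engineering rules is surfaced
#' here with its standard value (20 m2 small-polygon cut-off, 10-m
#' rasterization, 40-m / 2-m / 100-m filters, 20-m absence grid, 2/3
#' training split, 0.95 target sensitivity).
#'
#' @param preset `"original"` or `"final"`.
#' @param landscape a [landscape_config()]. The workflow default is a
#'   3 x 3 km extent on 10-m cells: large enough that the 100-m
#'   background-exclusion rule leaves most of the landscape available,
#'   while keeping the grid near 300 x 300 cells so a full run stays
#'   interactive.
#' @param truth_coefficients named effects (logit scale, per SD) defining
#'   the virtual species.
#' @param truth_intercept logit-scale intercept of the truth.
#' @param n_point_obs number of direct point observations to simulate.
#' @param n_polygons,polygon_radius_m simulated subpopulation polygons.
#' @param background_ratio background+absence points per presence point
#'   (the ratio is preserved across presets so AUC-PR stays comparable).
#' @param n_survey_cells survey cells for the field-validation stage
#'   (0 disables it).
#' @param target_sensitivity fixed sensitivity for thresholding.
#' @param train_fraction training share of the split.
#' @param small_area_m2,polygon_grid_m,polygon_thin_m,presence_thin_m,
#'   exclusion_radius_m,absence_grid_m,survey_cell_m point-engineering
#'   constants.
#' @param predict_rasters if `TRUE`, member and ensemble rasters are
#'   computed (needed for area accounting and survey validation).
#' @param model_seeds seed passed to model fitting.
#' @param seed master seed.
#' @return A `workflow_config` list.
#' @export
workflow_config <- function(preset = c("final", "original"),
                            landscape = landscape_config(
                              width_m = 3000, height_m = 3000,
                              cell_size_m = 10, relief_amplitude_m = 120,
                              roughness = 0.2),
                            truth_coefficients = c(geology_class = -3,
                                                   northness = 1.5),
                            truth_intercept = -1,
                            n_point_obs = 400,
                            n_polygons = 6,
                            polygon_radius_m = 25,
                            background_ratio = 3,
                            n_survey_cells = 0,
                            target_sensitivity = 0.95,
                            train_fraction = 2 / 3,
                            small_area_m2 = 20,
                            polygon_grid_m = 10,
                            polygon_thin_m = 40,
                            presence_thin_m = 2,
                            exclusion_radius_m = 100,
                            absence_grid_m = 20,
                            survey_cell_m = 50,
                            predict_rasters = TRUE,
                            model_seeds = 1L,
                            seed = 1L) {
  preset <- match.arg(preset)
  models <- if (preset == "original") {
    c("rf_downsampled", "rf_shallow", "brt", "maxent")
  } else {
    c("rf_downsampled", "brt", "maxent", "mars", "gam")
  }
  include <- if (preset == "original") {
    c("rf_downsampled", "rf_shallow", "brt")
  } else models
  structure(
    list(preset = preset, landscape = landscape,
         truth_coefficients = truth_coefficients,
         truth_intercept = truth_intercept,
         n_point_obs = n_point_obs, n_polygons = n_polygons,
         polygon_radius_m = polygon_radius_m,
         background_ratio = background_ratio,
         n_survey_cells = n_survey_cells,
         target_sensitivity = target_sensitivity,
         train_fraction = train_fraction,
         small_area_m2 = small_area_m2, polygon_grid_m = polygon_grid_m,
         polygon_thin_m = polygon_thin_m,
         presence_thin_m = presence_thin_m,
         exclusion_radius_m = exclusion_radius_m,
         absence_grid_m = absence_grid_m, survey_cell_m = survey_cell_m,
         predict_rasters = predict_rasters,
         models = models, include_in_ensemble = include,
         model_seeds = model_seeds, seed = as.integer(seed)),
    class = "workflow_config"
  )
}

#' Build the covariate stack for a synthetic landscape
#'
#' Generates DEM, geology, precipitation (and, for the `final` preset,
#' spectral bands) and derives the aligned covariate stack: elevation,
#' slope, northness, eastness, bilinearly resampled precipitation,
#' ordinal geology distance class and (final preset) soil colour index.
#'
#' @param config a [workflow_config()].
#' @return A list: `stack` ([covariate_stack()]), `geology` (polygons +
#'   mask), `dem`.
#' @export
build_synthetic_stack <- function(config) {
  lc <- config$landscape
  dem <- generate_dem(lc)
  geol <- generate_geology(lc)
  precip_coarse <- generate_precipitation(lc)
  asp <- aspect_components(dem)
  layers <- list(
    elevation = dem,
    slope = compute_slope(dem),
    northness = asp$northness,
    eastness = asp$eastness,
    precipitation = resample_bilinear(precip_coarse, dem),
    geology_class = geology_distance_classes(geol$mask)
  )
  if (config$preset == "final") {
    bands <- generate_spectral_bands(geol$mask, seed = lc$seed)
    layers$soil_color_index <- soil_color_index(bands$red, bands$green)
  }
  list(stack = covariate_stack(layers), geology = geol, dem = dem)
}

# assemble labelled points for one preset; returns occurrence data.frame
build_point_sets <- function(config, stack, truth) {
  lc <- config$landscape
  occ <- sample_virtual_species(truth, config$n_point_obs,
                                config$n_polygons,
                                config$polygon_radius_m, seed = lc$seed)
  point_obs <- if (nrow(occ$points)) {
    data.frame(x = occ$points$x, y = occ$points$y, label = "presence",
               source = "point_obs")
  } else {
    data.frame(x = numeric(), y = numeric(), label = character(),
               source = character())
  }
  if (config$preset == "original") {
    # sparse manually-placed points inside subpopulation polygons,
    # approximated by polygon sampling thinned to a 10-m minimum distance
    poly_pts <- polygon_to_points(occ$polygons,
                                  small_area_m2 = config$small_area_m2,
                                  grid_m = config$polygon_grid_m,
                                  thin_m = config$polygon_grid_m)
    presences <- rbind(point_obs,
                       poly_pts[, c("x", "y", "label", "source")])
    presences$point_id <- seq_len(nrow(presences))
  } else {
    poly_pts <- polygon_to_points(occ$polygons,
                                  small_area_m2 = config$small_area_m2,
                                  grid_m = config$polygon_grid_m,
                                  thin_m = config$polygon_thin_m)
    presences <- assemble_presences(point_obs, poly_pts,
                                    thin_m = config$presence_thin_m)
  }
  valid_mask <- grid_raster(
    matrix(1, nrow(truth$suitability$values),
           ncol(truth$suitability$values)),
    lc$xmin, lc$ymin, lc$cell_size_m)
  absences <- data.frame()
  if (config$preset == "final" && config$n_survey_cells > 0) {
    cells <- generate_survey_cells(truth$suitability,
                                   n_cells = config$n_survey_cells,
                                   cell_size_m = config$survey_cell_m,
                                   seed = lc$seed)
    absences <- absence_from_survey(cells,
                                    cell_size_m = config$survey_cell_m,
                                    grid_m = config$absence_grid_m)
  }
  if (config$preset == "final" && nrow(absences))
    absences <- exclusion_filter(absences, presences,
                                 config$exclusion_radius_m)
  # top up the background draw until presence:(background+absence) hits the
  # configured ratio even after the exclusion filter removes candidates
  n_target <- max(2L, round(nrow(presences) * config$background_ratio) -
                    nrow(absences))
  background <- NULL
  for (round_i in seq_len(20L)) {
    short <- n_target - if (is.null(background)) 0L else nrow(background)
    if (short <= 0) break
    draw <- generate_background(valid_mask, max(short * 2L, 10L),
                                seed = lc$seed + round_i - 1L)
    if (config$preset == "final")
      draw <- exclusion_filter(draw, presences, config$exclusion_radius_m)
    background <- rbind(background, draw)
  }
  if (is.null(background) || nrow(background) < 2L)
    stop("background generation failed: exclusion filter removed nearly ",
         "all candidates (landscape too small for the exclusion radius?)",
         call. = FALSE)
  background <- utils::head(background, n_target)
  cols <- c("x", "y", "label", "source")
  pts <- rbind(presences[, cols], background[, cols],
               if (nrow(absences)) absences[, cols])
  pts$point_id <- seq_len(nrow(pts))
  pts[, c("point_id", cols)]
}

#' Run an end-to-end workflow on a synthetic landscape
#'
#' Generates the landscape, derives covariates, defines the virtual
#' species truth, engineers point sets under the preset's rules, splits
#' them, fits the preset's model suite, validates on the held-out third,
#' builds the AUC-PR-weighted ensemble, thresholds it at the target
#' sensitivity, and — when survey cells are requested and rasters are on —
#' runs the field-validation statistics against survey cells whose
#' detections are drawn from the truth. Fully deterministic under the
#' config seed.
#'
#' @param config a [workflow_config()].
#' @return A `workflow_run` list with elements `config`, `stack`,
#'   `truth`, `points`, `split`, `models`, `metrics` (with normalized
#'   averages; includes the ensemble row), `weights`,
#'   `importance`, `threshold`, and optionally `ensemble_raster`, `area`,
#'   `survey`.
#' @export
run_workflow <- function(config) {
  built <- build_synthetic_stack(config)
  stack <- built$stack
  truth <- define_true_suitability(stack$layers,
                                   config$truth_coefficients,
                                   config$truth_intercept)
  pts <- build_point_sets(config, stack, truth)
  ext <- extract_covariates(pts, stack)
  split <- split_train_validation(ext$data,
                                  train_fraction = config$train_fraction,
                                  seed = config$seed)
  y_val <- response_01(split$validation)
  models <- list(); val_pred <- list(); train_pred <- list()
  metrics <- NULL
  for (alg in config$models) {
    m <- fit_sdm(split$train, model_spec(alg, seed = config$model_seeds))
    models[[alg]] <- m
    val_pred[[alg]] <- predict_points(m, split$validation)
    train_pred[[alg]] <- predict_points(m, split$train)
    metrics <- rbind(metrics, metric_row(alg, val_pred[[alg]], y_val))
  }
  auc_pr_by_model <- stats::setNames(metrics$auc_pr, metrics$model_id)
  weights <- ensemble_weights(auc_pr_by_model,
                              include = config$include_in_ensemble)
  ens_val <- ensemble_predict(val_pred, weights)
  ens_train <- ensemble_predict(train_pred, weights)
  metrics <- rbind(metrics, metric_row("ensemble", ens_val, y_val))
  metrics <- normalized_average(metrics)
  thr <- fixed_sensitivity_threshold(
    ens_train[split$train$label == "presence"],
    target = config$target_sensitivity)
  out <- list(config = config, stack = stack, truth = truth,
              geology = built$geology, points = pts, split = split,
              models = models, metrics = metrics, weights = weights,
              validation_predictions = c(val_pred,
                                         list(ensemble = ens_val)),
              threshold = thr,
              importance = lapply(models, variable_importance))
  if (config$predict_rasters) {
    member_rasters <- lapply(models[config$include_in_ensemble],
                             predict_raster, stack = stack)
    out$ensemble_raster <- ensemble_predict(member_rasters, weights)
    out$area <- classify_and_account(
      out$ensemble_raster, thr$threshold,
      scores = ens_val, labels = y_val)
    if (config$n_survey_cells > 0) {
      cells <- generate_survey_cells(truth$suitability,
                                     n_cells = config$n_survey_cells,
                                     cell_size_m = config$survey_cell_m,
                                     seed = config$seed + 1L)
      cells <- cell_suitability(out$ensemble_raster, cells,
                                cell_size_m = config$survey_cell_m)
      out$survey <- list(cells = cells,
                         summary = summarize_survey(
                           cells, cell_size_m = config$survey_cell_m),
                         contingency = tryCatch(
                           threshold_contingency(cells, thr$threshold),
                           error = function(e) NULL))
    }
  }
  class(out) <- "workflow_run"
  out
}

#' @export
print.workflow_run <- function(x, ...) {
  cat(sprintf("<workflow_run> preset = %s, %d models + ensemble\n",
              x$config$preset, length(x$models)))
  print(x$metrics[, c("model_id", "auc_roc", "auc_pr", "pearson_r",
                      "average")], digits = 3)
  invisible(x)
}

#' Presence-background habitat comparison
#'
#' Per-covariate comparison of presence versus background values: group
#' means, one-sided rank-sum p (presence greater) and Cliff's delta —
#' the tabular summary of which habitat axes separate the species from
#' the landscape.
#'
#' @param data extracted covariate table with a `label` column.
#' @return A data.frame with one row per covariate.
#' @export
habitat_characteristics <- function(data) {
  covs <- covariate_columns(data)
  pres <- data[data$label == "presence", , drop = FALSE]
  bg <- data[data$label != "presence", , drop = FALSE]
  do.call(rbind, lapply(covs, function(cv) {
    w <- stats::wilcox.test(pres[[cv]], bg[[cv]])
    data.frame(covariate = cv,
               mean_presence = mean(pres[[cv]]),
               mean_background = mean(bg[[cv]]),
               cliffs_delta = cliffs_delta(pres[[cv]], bg[[cv]]),
               wilcoxon_p = w$p.value)
  }))
}

#' Write workflow reports
#'
#' Renders the run's tables to plain files in `dir`: the validation
#' metric table (column order AUC-ROC, AUC-PR, correlation, normalized
#' average), per-model variable-importance ranks, ensemble weights, the
#' threshold report, the presence/background habitat comparison and, if
#' present, the field-survey summary. Regeneration is idempotent.
#'
#' @param run a `workflow_run`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
render_report <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- run$metrics[, c("model_id", "auc_roc", "auc_pr", "pearson_r",
                       "average")]
  names(m) <- c("model", "AUC-ROC", "AUC-PR", "Correlation",
                "Normalized average")
  utils::write.csv(m, file.path(dir, "validation_metrics.csv"),
                   row.names = FALSE)
  imp <- do.call(rbind, lapply(names(run$importance), function(id) {
    d <- run$importance[[id]]
    d$model <- id
    d
  }))
  utils::write.csv(imp, file.path(dir, "variable_importance.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(model = names(run$weights),
                              weight = as.numeric(run$weights)),
                   file.path(dir, "ensemble_weights.csv"),
                   row.names = FALSE)
  thr <- run$threshold
  thr_report <- list(threshold = thr$threshold,
                     target_sensitivity = thr$target_sensitivity,
                     achieved_sensitivity = thr$achieved_sensitivity)
  if (!is.null(run$area)) {
    thr_report$suitable_fraction <- run$area$suitable_fraction
    thr_report$suitable_km2 <- run$area$suitable_km2
    thr_report$suitable_acres <- run$area$suitable_acres
    thr_report$sensitivity_validation <- run$area$sensitivity
    thr_report$specificity_validation <- run$area$specificity
  }
  jsonlite::write_json(thr_report, file.path(dir, "threshold.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(habitat_characteristics(run$split$validation),
                   file.path(dir, "habitat_characteristics.csv"),
                   row.names = FALSE)
  if (!is.null(run$survey)) {
    s <- run$survey$summary
    jsonlite::write_json(unclass(s)[!vapply(unclass(s), is.null, TRUE)],
                         file.path(dir, "survey_validation.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a workflow configuration from YAML
#'
#' All keys of [workflow_config()] (and the nested `landscape` keys of
#' [landscape_config()]) may appear in the file; missing keys take their
#' defaults.
#'
#' @param path YAML file.
#' @return A `workflow_config`.
#' @export
read_workflow_config <- function(path) {
  y <- yaml::read_yaml(path)
  ls_args <- y$landscape
  y$landscape <- if (is.null(ls_args)) landscape_config() else
    do.call(landscape_config, ls_args)
  if (!is.null(y$truth_coefficients))
    y$truth_coefficients <- unlist(y$truth_coefficients)
  do.call(workflow_config, y)
}
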