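# ensdm — ensemble species distribution modelling with field validation

`ensdm` is an R package for presence-background species distribution
modelling (SDM) of narrow-range species on high-resolution terrain, built
around the workflow used in field-validated habitat assessments of rare
plants on distinctive geologic substrates: derive terrain and substrate
covariates from gridded inputs, engineer presence / background /
true-absence point sets under explicit spatial rules, fit a suite of
suitability models behind one uniform contract, combine them into an
AUC-PR-weighted ensemble, convert the continuous ensemble into a binary
habitat map at a fixed sensitivity, and validate predictions against
systematically surveyed cells.

Every stage is exercisable end-to-end on synthetic landscapes with a known
habitat truth, so the whole pipeline is testable without any external
downloads.

## The core method

**Covariates.** From a fine-resolution DEM the package derives slope
(Horn's 3×3 stencil, degrees) and the two linearized aspect components

```
northness = cos(aspect · π/180),   eastness = sin(aspect · π/180)
```

plus an ordinal *geology distance class* from a focal formation mask
(class 1: 0–1 m from the formation, 2: 1–10 m, 3: 10–100 m, 4: >100 m,
via an exact Euclidean distance transform), a bilinearly resampled coarse
precipitation surface, and a soil colour index `(R − G)/(R + G)` from red
and green reflectance bands.

**Point engineering.** Mapped subpopulation polygons smaller than 20 m²
contribute their centroid; larger ones are rasterized on a 10-m grid and
their cell centroids thinned to a 40-m minimum distance. Merged presences
are thinned at 2 m; background and survey-derived true-absence points
(20-m grid over surveyed-minus-detected area) are excluded within 100 m of
any presence; the presence:(background+absence) ratio is preserved so
AUC-PR values stay comparable across workflow versions.

**Models and ensemble.** Six algorithms share one fit/predict contract:
downsampled random forest (equal class counts per tree), shallow random
forest (depth ≤ 2), boosted regression trees, a regularized
presence-background logistic model with linear/quadratic/product features
("maxent"), multivariate adaptive regression splines, and a binomial GAM.
Validation uses only threshold-independent metrics — AUC-ROC, AUC-PR and
Pearson correlation — on a held-out third of the points. The ensemble is
the convex combination with weights

```
w_i = AUCPR_i / Σ_j AUCPR_j        (over the included models)
```

and models are ranked by the *normalized average*: min-max scale each
metric column across all models (ensemble included), then average the
three scaled values.

**Thresholding and field validation.** The suitable/unsuitable cutoff is
the largest score keeping sensitivity ≥ 0.95 on the training presences.
Field surveys of 50-m cells are compared against ensemble predictions with
a one-sided Wilcoxon rank-sum test, Cliff's delta effect size
(`d = P(X>Y) − P(X<Y)`), and a thresholded 2×2 chi-square with Cramér's V.

## Worked example

```r
library(ensdm)

cfg <- workflow_config(
  preset = "final",
  truth_coefficients = c(geology_class = -4, northness = 2),
  truth_intercept = -2,
  n_point_obs = 400, n_polygons = 5, n_survey_cells = 30,
  seed = 1)
run <- run_workflow(cfg)
print(run)
```

```
<workflow_run> preset = final, 5 models + ensemble
        model_id auc_roc auc_pr pearson_r average
1 rf_downsampled   0.984  0.947     0.921   0.521
2            brt   0.988  0.965     0.926   1.000
3         maxent   0.982  0.912     0.916   0.000
4           mars   0.986  0.937     0.921   0.530
5            gam   0.986  0.930     0.924   0.628
6       ensemble   0.986  0.949     0.925   0.767
```

The virtual species was planted on the synthetic geologic formation
(negative effect of geology distance class) with a preference for
north-facing terrain, and every model recovers it: AUC-ROC ≈ 0.98 for all
five algorithms, and the ensemble's AUC-PR (0.949) sits within 0.016 of
the best member. The normalized-average column ranks BRT first on this
landscape.

```r
print(run$threshold)
#> <threshold_result> t = 0.5229 (target sens 0.95, achieved 0.952)
print(run$area)
#>   suitable: 36.28% of valid cells, 3.265 km2 (807 acres)
#>   at points: sensitivity 0.942, specificity 0.976
print(run$survey$summary)
#> <field_validation> 30 cells (0.075 km2, 18.5 acres)
#>   detected 9 | undetected 21
#>   suitability: detected 0.888 (SD 0.123) vs undetected 0.157 (SD 0.325)
#>   one-sided rank-sum p = 4.47e-05, Cliff's delta = 0.841
```

The 0.95-sensitivity cutoff (0.523 here) classifies 36% of this small,
formation-rich synthetic landscape as suitable, and simulated surveys of
50-m cells show detections concentrating strongly in predicted habitat —
a large Cliff's delta with a significant one-sided rank-sum test.

`render_report(run, "report/")` writes the metric table (column order
AUC-ROC, AUC-PR, Correlation, Normalized average), variable-importance
ranks, ensemble weights, the threshold report and the presence/background
habitat comparison as plain CSV/JSON files.

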