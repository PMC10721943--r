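---
title: "Methods: ensemble habitat suitability modelling with field validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble habitat suitability modelling with field validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ensdm)
```

## The modelling problem

`ensdm` implements a presence-background species distribution modelling
(SDM) workflow for narrow-range species whose habitat is controlled by
fine-scale terrain and a distinctive geologic substrate — the situation of
many rare edaphic endemics. Presence records (point observations plus
field-mapped subpopulation polygons) are contrasted against random
background points, and later against true absences from systematic
surveys, to estimate a continuous habitat-suitability surface, which is
finally thresholded into a binary suitable/unsuitable map for management
use.

Two workflow presets capture the two iterations such an effort typically
goes through. The `original` preset uses terrain + precipitation + geology
covariates, models the data with a downsampled random forest, a shallow
random forest, boosted regression trees and a regularized
presence-background logistic model, and leaves the latter out of the
ensemble. The `final` preset folds in what a field campaign adds — extra
presences, true absences from surveyed cells, a soil colour index
covariate — applies stricter point-engineering rules, and replaces the
shallow random forest with MARS and a GAM, including all five models in
the ensemble.

## Covariate derivation

Slope and aspect come from Horn's 3×3 finite-difference stencil with edge
replication; slope is `atan(|∇z|)` in degrees. Aspect is circular, so it
enters models only through `northness = cos(aspect)` and
`eastness = sin(aspect)` (radians); on flat cells, where aspect is
undefined, both components are set to 0 so flats contribute no directional
signal (the alternative — missing values — would discard flat terrain from
modelling entirely). The components satisfy `n² + e² = 1` on sloped cells
and 0 on flats, which the tests assert.

Geology enters as an ordinal distance class from the focal formation:
class 1 for distances in [0, 1) m (on or immediately adjacent), 2 for
[1, 10) m, 3 for [10, 100) m, 4 beyond. Distances are exact Euclidean
centre-to-centre distances from a two-pass Felzenszwalb distance
transform, checked against an exhaustive nearest-cell search in the test
suite. The class raster is carried as a numeric ordinal feature (its mean
over presences is a meaningful summary); distance is not geodesic because
the package contractually assumes a single projected CRS in metres and
rejects geographic inputs rather than reprojecting them.

Coarse layers (e.g. 800-m precipitation normals) are aligned to the fine
grid by cell-centre bilinear interpolation — exact on affine surfaces, and
extended by edge values outside the hull of coarse centres. Categorical
layers (formation mask, geology class) are never interpolated. The soil
colour index is `(R − G)/(R + G)` from red and green reflectance, high on
reddish soils and near zero on spectrally flat gray substrates; cells with
`R + G = 0` become missing. Covariate extraction at points uses the
containing cell (at 1–10 m resolution the difference from interpolated
lookup is negligible); points outside the grid or on missing cells are
excluded from modelling and reported with a reason.

## Point engineering

The point rules exist to keep dense field mapping from overwhelming the
models:

* polygons < 20 m² contribute exactly their centroid; larger polygons are
  rasterized on a 10-m grid (a cell is covered when its centre falls
  inside) and contribute covered-cell centroids, thinned to ≥ 40 m. A
  large polygon covering no cell centre, or losing all its points to
  thinning against earlier polygons, falls back to its centroid so every
  polygon contributes at least one point;
* merged presences are thinned to ≥ 2 m;
* true absences tile the surveyed-minus-detected area on a 20-m grid;
* background and absence candidates closer than 100 m to any presence are
  removed ("closer than" is strict: ties at exactly the radius survive);
* the presence:(background + absence) ratio is preserved by topping up the
  background draw after exclusion, so AUC-PR is comparable across presets.

Thinning is a greedy sequential scan in input order: deterministic,
order-stable, and guaranteed to leave pairwise distances at or above the
minimum. The source order of the scan is part of the algorithm's
definition; a seeded shuffle is exposed for sensitivity analysis. The
train/validation split is stratified by label at a 2/3 fraction and
seeded.

## Models

All six algorithms share a fit/predict contract (scores in [0, 1],
stateless prediction), so the ensemble layer never branches on algorithm:

* **rf_downsampled** — `randomForest` with per-tree stratified bootstrap of
  equal class counts (500 trees), the standard remedy for extreme
  presence:background imbalance;
* **rf_shallow** — `ranger` with `max.depth = 2` (500 trees, impurity
  importance);
* **brt** — gradient-boosted trees via `xgboost`: 1000 staged trees,
  learning rate 0.01, depth 3, bag fraction 0.5, single-threaded for
  reproducibility;
* **maxent** — an L1-regularized presence-background logistic model on
  linear, quadratic and pairwise-product features of the standardized
  covariates (`glmnet`), with the penalty chosen by BIC along the
  regularization path. The BIC rule keeps model selection deterministic
  where cross-validation would inject randomness. Output is on the
  response (probability) scale;
* **mars** — a package-authored multivariate adaptive regression spline
  fitter: forward selection of reflected hinge pairs (interactions up to
  degree 2, candidate knots at interior deciles) scored against current
  residuals, followed by backward pruning on the generalized
  cross-validation criterion with the conventional penalty of 3 effective
  parameters per knot; least-squares on the 0/1 response with predictions
  clipped to [0, 1];
* **gam** — `mgcv` binomial GAM with thin-plate smooths (basis size capped
  by the number of distinct values; covariates with < 4 distinct values,
  such as the ordinal geology class on formation-dominated landscapes,
  enter linearly).

Variable importance is each algorithm's native measure (Gini decrease,
impurity, gain, coefficient mass, GCV-surviving coefficient mass,
smooth-term chi-square) converted to dense ranks; covariates a pruned or
regularized model never uses are reported unranked rather than tied last.

## Validation, ensembling, thresholding

Only threshold-independent metrics are used: AUC-ROC (the Mann-Whitney
probability with midrank tie handling), AUC-PR in its average-precision
form (tie blocks scored at the block end; trapezoidal interpolation in PR
space is optimistic and deliberately avoided), and Pearson correlation of
scores against the 0/1 labels, which is sensitive to calibration. AUC-PR
leads because the positives are rare: its random-ranking baseline is the
prevalence, not 0.5.

The ensemble weight of model *i* is `AUCPR_i / Σ_j AUCPR_j` over the
included models; the ensemble prediction is the corresponding convex
combination of member scores. The normalized average ranks models across
metrics: each metric column is min-max scaled to [0, 1] **across all rows
including the ensemble row** — including it is what makes the published
reference-table values reproduce exactly — and the three scaled values are
averaged; a zero-range column contributes 0.5 to every model.

The suitable/unsuitable cutoff fixes sensitivity rather than accuracy: for
a rare species, misclassifying true habitat as unsuitable is far costlier
than the reverse. The threshold is the largest observed score `t` with
`#(presence scores ≥ t)/n ≥ 0.95`, candidates being the observed scores
plus 0 and 1 (no interpolation between scores); classification is
`score ≥ t`, so ties fall on the suitable side. The threshold is computed
on the training presences of the surface being thresholded; suitable area
is reported as a fraction of valid cells, in km², and in acres at
247.10538 acres/km² (rounded to the nearest acre).

## Field validation

Survey cells (50-m squares on a grid aligned with the prediction raster)
carry a detection flag; undetected surveyed cells are treated as true
absences — imperfect detection is out of scope. Each cell's suitability is
the mean of valid fine-grid predictions inside it (max and centre-cell
summaries are available as options). Detected and undetected cells are
compared with a one-sided Wilcoxon rank-sum test (`stats::wilcox.test`:
exact for small untied samples, normal approximation with tie correction
otherwise) and Cliff's delta, computed via the rank identity
`d = 2U/(mn) − 1`, which equals all-pairs enumeration exactly. The
thresholded 2×2 contingency analysis uses a Pearson chi-square without
continuity correction (counts are typically large), with Fisher's exact p
reported alongside whenever an expected count drops below 5; Cramér's V
for a 2×2 table is `sqrt(χ²/n)`.

## The synthetic landscape

The generator emulates the study system every stage expects, with a known
truth so recovery is checkable:

* **DEM** — low-pass-filtered Gaussian noise (kernel bandwidth =
  1/roughness cells) rescaled to a configured relief amplitude; zero
  amplitude gives a perfectly flat surface. The default
  `landscape_config()` uses 1-m cells, matching the LiDAR-derived DEMs
  such studies build on.
* **Geology** — irregular star-shaped "badland" blobs grown until the
  formation occupies the target fraction of cell centres (default 0.3, a
  minority of the extent); the polygon set and raster mask are consistent
  by construction.
* **Precipitation** — a coarse (800-m) raster running linearly from 220 mm
  on the north edge to 320 mm on the south, the range and orientation of
  the semi-arid gradient the workflow was designed around (millimetres
  internally; such gradients are usually quoted in cm).
* **Spectral bands** — two-level red/green reflectance (elevated soil
  colour index on-formation) plus Gaussian noise (SD 0.02 by default).
* **Virtual species** — true suitability is the inverse logit of a linear
  combination of standardized covariates; presences are sampled with
  probability proportional to suitability and jittered within cells;
  subpopulation polygons are blobs centred on high-suitability cells.
* **Survey cells** — non-overlapping 50-m cells placed uniformly (or
  suitability-weighted, emulating targeted surveys — the placement policy
  is configurable because survey designs differ), with detections drawn
  from a configurable rule; the default is Bernoulli with probability
  equal to true suitability clipped to [0.01, 0.99], which keeps both
  detected and undetected cells represented.

All randomness flows from one master seed split into named substreams
(dem, geology, bands, species, survey, background, split, model), so each
stage is independently reproducible and two runs under one seed are
bit-identical end to end.

What the generator does **not** emulate: spatial sampling bias in
occurrence records, positional error, spatially autocorrelated detection
failure, mixed geologic gradients, or any real geographic CRS. Passing
tests on this landscape therefore demonstrate that the pipeline's
machinery is correct and that the models can recover a clean signal; they
say nothing about performance under the observation biases of real
occurrence data.

## Scale and numerical choices

The demonstration and test workflows run on a 3 × 3 km extent with 10-m
cells (a ~300 × 300 grid): large enough that the 100-m exclusion rule
leaves most of the landscape available for background points, small
enough that a full five-model run with rasters completes in seconds. The
strong-signal recovery scenario uses a steep two-covariate truth
(geology class −4, northness +2 per SD, intercept −2): a sharply
substrate-limited species, the regime this workflow targets. These sizes
and effects were fixed as the package's reference conditions when the
scenario was designed.

Other numerical decisions worth recording: the DEM field is rescaled by
range (not variance), making relief amplitude exact per realization;
bilinear edge handling extends border values rather than extrapolating;
the distance transform replaces infinities with a large finite constant
(1e12) to keep the parabola-intersection arithmetic finite; greedy
thinning ties ("exactly d apart") are kept; the stratified split rounds
the training count to the nearest integer but always leaves at least one
point per side; glmnet's lambda path is searched by BIC rather than CV;
and the MARS forward pass stops early when the best candidate pair's
residual-sum-of-squares reduction falls below 1e-10 of the response
energy, or when a new pair would make the design rank-deficient.

## Known limitations

* The MARS forward pass scores candidate hinge pairs against current
  residuals rather than refitting the full basis per candidate; this is
  faster and almost always selects the same knots, but is not guaranteed
  to match a full exhaustive forward pass.
* The "maxent" model is a regularized presence-background logistic
  approximation with linear/quadratic/product features; it does not
  implement hinge/threshold feature classes.
* No spatial cross-validation: the split is simple random (stratified by
  label), so validation metrics inherit any optimism from spatial
  autocorrelation between train and validation points — exactly the
  caveat that applies to the field-survey statistics when survey cells
  sit near known presences.
* Raster IO is the plain-text ESRI ASCII grid; the package neither reads
  nor writes GeoTIFF, and vector IO is GeoJSON/CSV.
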