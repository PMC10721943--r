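#' Model specification
#'
#' One uniform handle for every suitability algorithm in the suite. All
#' algorithms are fit on a presence (1) versus background/absence (0)
#' response and return scores in [0, 1] through the same predict contract,
#' so the ensemble layer never needs to branch on algorithm.
#'
#' Algorithms:
#' \describe{
#'   \item{rf_downsampled}{random forest in which each tree's bootstrap
#'     draws an equal number of presence and non-presence points, countering
#'     the extreme class imbalance of presence-background data.}
#'   \item{rf_shallow}{random forest whose trees are limited to a depth of
#'     two splits, trading variance for strong regularization.}
#'   \item{brt}{boosted regression trees: many shallow trees fit in stages
#'     with shrinkage and bagging.}
#'   \item{maxent}{an L1-regularized presence-background logistic model on
#'     linear, quadratic and pairwise-product features of the standardized
#'     covariates, with the penalty chosen by BIC along the regularization
#'     path; output on the probability scale.}
#'   \item{mars}{multivariate adaptive regression splines: forward
#'     selection of hinge-function bases (interactions up to degree 2)
#'     followed by generalized-cross-validation backward pruning.}
#'   \item{gam}{generalized additive model with smooth terms per covariate
#'     (binomial family, REML smoothness selection).}
#' }
#'
#' @param algorithm one of `"rf_downsampled"`, `"rf_shallow"`, `"brt"`,
#'   `"maxent"`, `"mars"`, `"gam"`.
#' @param hyperparameters named list overriding algorithm defaults
#'   (`ntree`, `nrounds`, `eta`, `max_depth`, `subsample`, `nk`,
#'   `max_degree`, ...).
#' @param seed integer seed used by stochastic fitters.
#' @return A `model_spec`.
#' @export
model_spec <- function(algorithm, hyperparameters = list(), seed = 1L) {
  algorithms <- c("rf_downsampled", "rf_shallow", "brt", "maxent", "mars",
                  "gam")
  if (!algorithm %in% algorithms)
    stop("unknown algorithm: ", algorithm, call. = FALSE)
  structure(list(algorithm = algorithm, hyperparameters = hyperparameters,
                 seed = as.integer(seed)),
            class = "model_spec")
}

hp <- function(spec, name, default) {
  v <- spec$hyperparameters[[name]]
  if (is.null(v)) default else v
}

covariate_columns <- function(train) {
  setdiff(names(train), c("point_id", "label", "source", "x", "y"))
}

response_01 <- function(train) as.integer(train$label == "presence")

#' Fit a suitability model
#'
#' @param train data.frame with a `label` column (`"presence"` vs
#'   background/absence) and one numeric column per covariate; coordinate
#'   and id columns are ignored.
#' @param spec a [model_spec()].
#' @return A `fitted_sdm` holding the fitted object, the covariate names
#'   and a native variable-importance table; use [predict_points()] /
#'   [predict_raster()] to score.
#' @export
fit_sdm <- function(train, spec) {
  covs <- covariate_columns(train)
  if (!length(covs)) stop("no covariate columns in training table",
                          call. = FALSE)
  x <- as.matrix(train[, covs, drop = FALSE])
  if (any(!is.finite(x)))
    stop("training covariates contain non-finite values", call. = FALSE)
  y <- response_01(train)
  if (length(unique(y)) < 2)
    stop("training data contain a single class", call. = FALSE)
  if (sum(y == 1) < 10 || sum(y == 0) < 10)
    stop("need at least 10 presences and 10 non-presences", call. = FALSE)

  fit <- switch(
    spec$algorithm,
    rf_downsampled = {
      m <- min(table(y))
      yf <- factor(y, levels = c(0, 1))
      with_seed(substream_seed(spec$seed, "model"),
        randomForest::randomForest(
          x = as.data.frame(x), y = yf,
          ntree = hp(spec, "ntree", 500),
          sampsize = c(m, m), strata = yf, replace = TRUE,
          keep.inbag = TRUE))
    },
    rf_shallow = {
      d <- data.frame(.y = factor(y, levels = c(0, 1)), as.data.frame(x))
      ranger::ranger(.y ~ ., data = d, probability = TRUE,
                     num.trees = hp(spec, "ntree", 500),
                     max.depth = hp(spec, "max_depth", 2),
                     importance = "impurity",
                     seed = substream_seed(spec$seed, "model"),
                     num.threads = 1)
    },
    brt = {
      dtrain <- xgboost::xgb.DMatrix(x, label = y)
      with_seed(substream_seed(spec$seed, "model"),
        xgboost::xgb.train(
          params = list(objective = "binary:logistic",
                        eta = hp(spec, "eta", 0.01),
                        max_depth = hp(spec, "max_depth", 3),
                        subsample = hp(spec, "subsample", 0.5),
                        nthread = 1),
          data = dtrain, nrounds = hp(spec, "nrounds", 1000),
          verbose = 0))
    },
    maxent = fit_maxent_glmnet(x, y, spec),
    mars = fit_mars(x, y, spec),
    gam = fit_gam_binomial(x, y, spec)
  )
  structure(list(spec = spec, fit = fit, covariates = covs),
            class = "fitted_sdm")
}

#' @export
print.fitted_sdm <- function(x, ...) {
  cat(sprintf("<fitted_sdm> algorithm = %s; covariates: %s\n",
              x$spec$algorithm, paste(x$covariates, collapse = ", ")))
  invisible(x)
}

# ---- maxent-style regularized logistic -------------------------------------

maxent_features <- function(x, centers, scales) {
  z <- sweep(sweep(x, 2L, centers, "-"), 2L, scales, "/")
  covs <- colnames(x)
  feats <- list()
  for (v in covs) feats[[v]] <- z[, v]
  for (v in covs) feats[[paste0(v, "^2")]] <- z[, v]^2
  if (length(covs) > 1) {
    cmb <- utils::combn(covs, 2)
    for (i in seq_len(ncol(cmb)))
      feats[[paste0(cmb[1, i], ":", cmb[2, i])]] <-
        z[, cmb[1, i]] * z[, cmb[2, i]]
  }
  do.call(cbind, feats)
}

fit_maxent_glmnet <- function(x, y, spec) {
  centers <- colMeans(x)
  scales <- apply(x, 2L, stats::sd)
  scales[scales == 0] <- 1
  f <- maxent_features(x, centers, scales)
  path <- glmnet::glmnet(f, y, family = "binomial", alpha = 1,
                         nlambda = hp(spec, "nlambda", 60),
                         standardize = FALSE)
  dev <- (1 - path$dev.ratio) * path$nulldev
  bic <- dev + log(length(y)) * path$df
  s <- path$lambda[which.min(bic)]
  list(path = path, lambda = s, centers = centers, scales = scales,
       feature_names = colnames(f))
}

predict_maxent <- function(fit, x) {
  f <- maxent_features(x, fit$centers, fit$scales)
  as.numeric(stats::predict(fit$path, newx = f, s = fit$lambda,
                            type = "response"))
}

# ---- MARS (hinge-basis regression splines) ---------------------------------

hinge <- function(v, knot, dir) if (dir > 0) pmax(v - knot, 0) else
  pmax(knot - v, 0)

mars_design <- function(terms, x) {
  n <- nrow(x)
  cols <- lapply(terms, function(tm) {
    b <- rep(1, n)
    for (h in tm) b <- b * hinge(x[, h$var], h$knot, h$dir)
    b
  })
  mat <- do.call(cbind, c(list(rep(1, n)), cols))
  colnames(mat) <- NULL
  mat
}

mars_gcv <- function(rss, n, n_terms, penalty = 3) {
  # effective parameters: coefficients plus penalized knot count
  c_m <- (n_terms + 1) + penalty * n_terms / 2
  if (c_m >= n) return(Inf)
  (rss / n) / (1 - c_m / n)^2
}

fit_mars <- function(x, y, spec) {
  nk <- hp(spec, "nk", 15L)            # max basis terms (besides intercept)
  max_degree <- hp(spec, "max_degree", 2L)
  n_knots <- hp(spec, "n_knots", 7L)
  n <- nrow(x)
  covs <- colnames(x)
  knots <- lapply(covs, function(v) {
    q <- unique(stats::quantile(x[, v],
                                probs = seq(0.1, 0.9,
                                            length.out = n_knots),
                                names = FALSE))
    q[q > min(x[, v]) & q < max(x[, v])]
  })
  names(knots) <- covs

  terms <- list()        # each term: list of hinge factors (var, knot, dir)
  design <- mars_design(terms, x)
  qrd <- qr(design)
  resid <- qr.resid(qrd, y)

  while (length(terms) < nk - 1L) {
    best <- NULL
    # parent terms of degree < max_degree (intercept parent = NULL)
    parents <- c(list(NULL), terms[vapply(terms, length, 1L) < max_degree])
    for (pi in seq_along(parents)) {
      parent <- parents[[pi]]
      pb <- if (is.null(parent)) rep(1, n) else {
        b <- rep(1, n)
        for (h in parent) b <- b * hinge(x[, h$var], h$knot, h$dir)
        b
      }
      used_vars <- vapply(parent, `[[`, "", "var")
      for (v in setdiff(covs, used_vars)) {
        for (kn in knots[[v]]) {
          b1 <- pb * hinge(x[, v], kn, 1)
          b2 <- pb * hinge(x[, v], kn, -1)
          # score the reflected pair against the current residuals
          bm <- cbind(b1, b2)
          cp <- crossprod(bm)
          if (any(diag(cp) < 1e-10)) next
          rhs <- crossprod(bm, resid)
          beta <- tryCatch(solve(cp, rhs), error = function(e) NULL)
          if (is.null(beta)) next
          red <- sum(rhs * beta)
          if (is.null(best) || red > best$red)
            best <- list(red = red, parent = parent, var = v, knot = kn)
        }
      }
    }
    if (is.null(best) || best$red <= 1e-10 * sum(y^2)) break
    for (dir in c(1, -1))
      terms[[length(terms) + 1L]] <-
        c(best$parent, list(list(var = best$var, knot = best$knot,
                                 dir = dir)))
    design <- mars_design(terms, x)
    qrd <- qr(design)
    if (qrd$rank < ncol(design)) {    # drop the pair if collinear
      terms <- terms[seq_len(length(terms) - 2L)]
      break
    }
    resid <- qr.resid(qrd, y)
  }

  # backward pruning on GCV
  repeat {
    design <- mars_design(terms, x)
    rss <- sum(qr.resid(qr(design), y)^2)
    gcv_now <- mars_gcv(rss, n, length(terms))
    if (!length(terms)) break
    gcv_drop <- vapply(seq_along(terms), function(i) {
      d <- mars_design(terms[-i], x)
      mars_gcv(sum(qr.resid(qr(d), y)^2), n, length(terms) - 1L)
    }, 0)
    i_best <- which.min(gcv_drop)
    if (gcv_drop[i_best] <= gcv_now) terms <- terms[-i_best] else break
  }

  design <- mars_design(terms, x)
  coefs <- qr.coef(qr(design), y)
  coefs[is.na(coefs)] <- 0
  rss <- sum((y - design %*% coefs)^2)
  list(terms = terms, coefs = coefs, rss = rss, n = n,
       covariates = covs)
}

predict_mars <- function(fit, x) {
  d <- mars_design(fit$terms, x)
  pmin(pmax(as.numeric(d %*% fit$coefs), 0), 1)
}

# ---- GAM -------------------------------------------------------------------

fit_gam_binomial <- function(x, y, spec) {
  covs <- colnames(x)
  d <- data.frame(.y = y, as.data.frame(x))
  rhs <- vapply(covs, function(v) {
    nu <- length(unique(x[, v]))
    if (nu < 4) v else sprintf("s(%s, k = %d)", v,
                               min(hp(spec, "k", 10), nu - 1L))
  }, "")
  form <- stats::as.formula(paste(".y ~", paste(rhs, collapse = " + ")))
  mgcv::gam(form, data = d, family = stats::binomial(), method = "REML")
}

# ---- uniform prediction contract -------------------------------------------

#' Predict suitability at points
#'
#' Scores rows of a covariate table with a fitted model. Scores are always
#' in [0, 1] and prediction is stateless: re-scoring the same rows gives
#' identical results.
#'
#' @param model a `fitted_sdm`.
#' @param newdata data.frame containing the training covariate columns.
#' @return Numeric vector of suitability scores in [0, 1].
#' @export
predict_points <- function(model, newdata) {
  missing_cols <- setdiff(model$covariates, names(newdata))
  if (length(missing_cols))
    stop("newdata lacks covariate column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  x <- as.matrix(newdata[, model$covariates, drop = FALSE])
  p <- switch(
    model$spec$algorithm,
    rf_downsampled =
      stats::predict(model$fit, as.data.frame(x), type = "prob")[, "1"],
    rf_shallow =
      stats::predict(model$fit, data = as.data.frame(x),
                     num.threads = 1)$predictions[, "1"],
    brt = stats::predict(model$fit, xgboost::xgb.DMatrix(x)),
    maxent = predict_maxent(model$fit, x),
    mars = predict_mars(model$fit, x),
    gam = as.numeric(stats::predict(model$fit,
                                    newdata = as.data.frame(x),
                                    type = "response"))
  )
  as.numeric(pmin(pmax(p, 0), 1))
}

#' Predict suitability over a raster stack
#'
#' Evaluates the model cellwise over an aligned covariate stack,
#' processing the grid in row blocks so memory stays bounded. Cells
#' missing in any input layer are missing in the output.
#'
#' @param model a `fitted_sdm`.
#' @param stack a [covariate_stack()] whose layer names include the
#'   training covariates.
#' @param block_rows rows per evaluation block.
#' @return A `grid_raster` of suitability scores.
#' @export
predict_raster <- function(model, stack, block_rows = 64L) {
  missing_layers <- setdiff(model$covariates, stack$layer_names)
  if (length(missing_layers))
    stop("stack lacks layer(s): ", paste(missing_layers, collapse = ", "),
         call. = FALSE)
  base <- stack$layers[[1]]
  nr <- nrow(base$values); nc <- ncol(base$values)
  out <- matrix(NA_real_, nr, nc)
  for (start in seq(1L, nr, by = block_rows)) {
    rows <- start:min(start + block_rows - 1L, nr)
    block <- sapply(model$covariates, function(nm)
      as.vector(stack$layers[[nm]]$values[rows, , drop = FALSE]))
    block <- matrix(block, ncol = length(model$covariates),
                    dimnames = list(NULL, model$covariates))
    ok <- rowSums(!is.finite(block)) == 0
    scores <- rep(NA_real_, nrow(block))
    if (any(ok))
      scores[ok] <- predict_points(model,
                                   as.data.frame(block[ok, , drop = FALSE]))
    out[rows, ] <- matrix(scores, nrow = length(rows))
  }
  grid_raster(out, base$xmin, base$ymin, base$cellsize)
}

#' Variable importance ranks
#'
#' Converts each algorithm's native importance measure (impurity decrease
#' for tree models, gain for boosting, coefficient mass for the
#' regularized logistic model, residual-sum-of-squares contribution for
#' MARS, smooth-term chi-square for GAM) into dense ranks, 1 = most
#' important. Covariates the fitted model does not use (pruned or
#' regularized out) are unranked (`NA`).
#'
#' @param model a `fitted_sdm`.
#' @return A data.frame with `covariate`, `importance`, `rank`.
#' @export
variable_importance <- function(model) {
  covs <- model$covariates
  imp <- switch(
    model$spec$algorithm,
    rf_downsampled = {
      gi <- randomForest::importance(model$fit)[, "MeanDecreaseGini"]
      gi[covs]
    },
    rf_shallow = model$fit$variable.importance[covs],
    brt = {
      it <- xgboost::xgb.importance(model = model$fit)
      v <- stats::setNames(rep(NA_real_, length(covs)), covs)
      v[it$Feature] <- it$Gain
      v
    },
    maxent = {
      beta <- as.matrix(stats::coef(model$fit$path, s = model$fit$lambda))
      beta <- beta[rownames(beta) != "(Intercept)", 1]
      v <- stats::setNames(numeric(length(covs)), covs)
      for (fn in names(beta)) {
        if (beta[fn] == 0) next
        for (cv in covs)
          if (cv %in% strsplit(sub("\\^2$", "", fn), ":")[[1]])
            v[cv] <- v[cv] + abs(beta[fn])
      }
      v[v == 0] <- NA_real_
      v
    },
    mars = {
      used <- unique(unlist(lapply(model$fit$terms, function(tm)
        vapply(tm, `[[`, "", "var"))))
      v <- stats::setNames(rep(NA_real_, length(covs)), covs)
      # deterministic contribution: coefficient mass of the basis terms
      # touching each covariate (pruned-out covariates stay unranked)
      for (cv in used) {
        touching <- vapply(model$fit$terms, function(tm)
          cv %in% vapply(tm, `[[`, "", "var"), TRUE)
        v[cv] <- sum(abs(model$fit$coefs[-1][touching]))
      }
      v
    },
    gam = {
      sm <- summary(model$fit)
      v <- stats::setNames(rep(NA_real_, length(covs)), covs)
      st <- sm$s.table
      if (!is.null(st) && nrow(st)) {
        nm <- gsub("^s\\(|,.*$|\\)$", "", rownames(st))
        v[nm] <- st[, "Chi.sq"]
      }
      pt <- sm$p.table
      lin <- setdiff(rownames(pt), "(Intercept)")
      if (length(lin)) v[lin] <- pt[lin, "z value"]^2
      v
    }
  )
  imp <- as.numeric(imp)
  rk <- rep(NA_integer_, length(covs))
  ranked <- which(!is.na(imp))
  if (length(ranked)) {
    o <- sort(unique(-imp[ranked]))
    rk[ranked] <- match(-imp[ranked], o)
  }
  data.frame(covariate = covs, importance = imp, rank = rk)
}
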