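ALGORITHMS <- c("rf_downsampled", "rf_shallow", "brt", "maxent", "mars",
                "gam")

test_that("every algorithm separates separable data and scores in [0,1]", {
  train <- make_separable_train(30)
  for (alg in ALGORITHMS) {
    m <- fit_sdm(train, model_spec(alg, seed = 1))
    p <- predict_points(m, train)
    expect_true(all(p >= 0 & p <= 1), info = alg)
    expect_equal(auc_roc(p, train$label == "presence"), 1, info = alg)
    # stateless prediction: re-scoring is bit-identical
    expect_identical(p, predict_points(m, train), info = alg)
  }
})

test_that("degenerate training inputs are rejected", {
  train <- make_separable_train(30)
  single <- train[train$label == "presence", ]
  expect_error(fit_sdm(single, model_spec("brt")), "single class")
  tiny <- train[c(1:5, 31:35), ]
  expect_error(fit_sdm(tiny, model_spec("gam")), "at least 10")
  bad <- train
  bad$a[3] <- Inf
  expect_error(fit_sdm(bad, model_spec("mars")), "non-finite")
})

test_that("shallow random forest trees never exceed depth two", {
  train <- make_separable_train(40)
  m <- fit_sdm(train, model_spec("rf_shallow", seed = 3))
  for (tree in seq_len(5)) {
    info <- ranger::treeInfo(m$fit, tree)
    # depth <= 2 means any node's children are at most two levels down:
    # with at most 2 split levels there can be at most 7 nodes
    expect_lte(nrow(info), 7)
  }
})

test_that("downsampled random forest balances classes in every bootstrap", {
  train <- make_separable_train(60)
  train$label[1:15] <- "background"   # 45 presences vs 75 background
  m <- fit_sdm(train, model_spec("rf_downsampled", seed = 2))
  inbag <- m$fit$inbag
  y <- train$label == "presence"
  n_min <- min(sum(y), sum(!y))
  draws_pres <- colSums(inbag[y, , drop = FALSE])
  draws_bg <- colSums(inbag[!y, , drop = FALSE])
  expect_true(all(draws_pres == n_min))
  expect_true(all(draws_bg == n_min))
})

test_that("seeded refits are reproducible for the stochastic fitters", {
  train <- make_separable_train(40)
  for (alg in c("rf_downsampled", "rf_shallow", "brt")) {
    p1 <- predict_points(fit_sdm(train, model_spec(alg, seed = 9)), train)
    p2 <- predict_points(fit_sdm(train, model_spec(alg, seed = 9)), train)
    expect_identical(p1, p2, info = alg)
  }
})

test_that("raster prediction agrees with point prediction and carries NA", {
  train <- make_separable_train(30)
  m <- fit_sdm(train, model_spec("gam", seed = 1))
  a_vals <- matrix(seq(-2, 2, length.out = 144), 12, 12)
  b_vals <- matrix(0.3, 12, 12)
  a_vals[4, 7] <- NA
  stack <- make_stack(list(a = a_vals, b = b_vals))
  r <- predict_raster(m, stack, block_rows = 5)
  expect_true(is.na(r$values[4, 7]))
  cc <- cell_centers(stack$layers$a)
  ok <- !is.na(cc$value)
  direct <- predict_points(m, data.frame(a = cc$value[ok],
                                         b = 0.3))
  expect_equal(r$values[cbind(cc$row[ok], cc$col[ok])], direct)
})

test_that("variable importance ranks the driving covariate first", {
  train <- withr::with_seed(5, {
    n <- 400
    a <- rnorm(n)
    b <- rnorm(n)
    pr <- plogis(3 * a)
    data.frame(label = ifelse(runif(n) < pr, "presence", "background"),
               a = a, b = b)
  })
  for (alg in c("rf_downsampled", "brt", "maxent", "gam")) {
    imp <- variable_importance(fit_sdm(train, model_spec(alg, seed = 4)))
    expect_equal(imp$rank[imp$covariate == "a"], 1L, info = alg)
  }
})

test_that("covariates a model never uses are reported unranked", {
  train <- make_separable_train(50)
  train$c <- 0.5   # constant covariate: no MARS knots, glmnet zero path
  mars_imp <- variable_importance(fit_sdm(train, model_spec("mars")))
  expect_true(is.na(mars_imp$rank[mars_imp$covariate == "c"]))
  expect_false(is.na(mars_imp$rank[mars_imp$covariate == "a"]))
  maxent_imp <- variable_importance(fit_sdm(train, model_spec("maxent")))
  expect_true(is.na(maxent_imp$rank[maxent_imp$covariate == "c"]))
})

test_that("prediction rejects schema mismatches", {
  train <- make_separable_train(30)
  m <- fit_sdm(train, model_spec("maxent"))
  expect_error(predict_points(m, data.frame(a = 1)), "lacks covariate")
  stack <- make_stack(list(a = matrix(0, 5, 5)))
  expect_error(predict_raster(m, stack), "lacks layer")
})
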