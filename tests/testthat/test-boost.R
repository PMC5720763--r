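test_that("a separable occurrence problem is fit to training AUC 1", {
  set.seed(1)
  X <- cbind(x1 = rep(c(0, 1), each = 40), x2 = rnorm(80))
  y <- X[, "x1"]
  fit <- suppressWarnings(
    fit_component(X, y, "bernoulli", tc = 1, lr = 0.3, bf = 1,
                  cv_folds = 3, seed = 1)
  )
  expect_equal(fit$train_metric, 1.0)
})

test_that("a constant gaussian response is flagged degenerate", {
  set.seed(2)
  X <- cbind(x1 = rnorm(60), x2 = rnorm(60))
  y <- rep(3, 60)
  fit <- suppressWarnings(
    fit_component(X, y, "gaussian", tc = 2, lr = 0.1, bf = 0.8,
                  cv_folds = 3, seed = 2)
  )
  expect_true(fit$degenerate)
  expect_true(is.na(fit$train_metric))
  expect_warning(infl <- relative_influence(fit), "degenerate")
  expect_true(all(infl$influence == 0))
  expect_true(isTRUE(attr(infl, "degenerate")))
})

test_that("CV deviance of a real signal beats the intercept-only null", {
  set.seed(3)
  n <- 500
  X <- cbind(x1 = runif(n, -2, 2), x2 = runif(n, -2, 2))
  y <- sin(2 * X[, "x1"]) + rnorm(n, 0, 0.3)
  fit <- suppressWarnings(
    fit_component(X, y, "gaussian", tc = 2, lr = 0.1, bf = 0.7,
                  cv_folds = 5, seed = 3)
  )
  # null deviance computed directly from y (gaussian deviance = MSE)
  null_dev <- mean((y - mean(y))^2)
  expect_lt(fit$cv_deviance_mean, null_dev)
})

test_that("too few cases per class refuses stratified CV", {
  X <- cbind(x1 = rnorm(20))
  y <- c(rep(0, 18), 1, 1)
  expect_error(
    fit_component(X, y, "bernoulli", tc = 1, lr = 0.1, bf = 1,
                  cv_folds = 5, seed = 1),
    "stratify"
  )
})

test_that("fitting is deterministic given the seed", {
  sys <- tiny_system()
  X <- as.matrix(sys$samples[, c("x1", "x2")])
  y <- as.integer(sys$samples$cpue > 0)
  f1 <- suppressWarnings(fit_component(X, y, "bernoulli", 2, 0.1, 0.7,
                                       cv_folds = 3, seed = 9))
  f2 <- suppressWarnings(fit_component(X, y, "bernoulli", 2, 0.1, 0.7,
                                       cv_folds = 3, seed = 9))
  expect_identical(component_response <- predict(f1$booster, X),
                   predict(f2$booster, X))
  expect_identical(f1$cv_curve, f2$cv_curve)
})

test_that("grid search fits every combination and picks by CV deviance,
           invariant to candidate ordering", {
  sys <- tiny_system()
  cfg <- brt_config(tc = c(2, 13), lr = c(0.01, 0.005), bf = 0.6,
                    cv_folds = 3, seed = 5, simplify = FALSE)
  gs <- suppressWarnings(grid_search(sys$samples, "cpue",
                                     attr(sys$samples, "expvars"), cfg))
  expect_equal(nrow(gs$trail), 8)  # 4 combos x 2 components
  expect_equal(sum(gs$trail$selected[gs$trail$component == "binary"]), 1)
  expect_equal(sum(gs$trail$selected[gs$trail$component == "gaussian"]), 1)

  cfg_rev <- brt_config(tc = c(13, 2), lr = c(0.005, 0.01), bf = 0.6,
                        cv_folds = 3, seed = 5, simplify = FALSE)
  gs_rev <- suppressWarnings(grid_search(sys$samples, "cpue",
                                         attr(sys$samples, "expvars"),
                                         cfg_rev))
  for (comp in c("binary", "gaussian")) {
    expect_identical(
      gs[[comp]][c("tc", "lr", "bf", "n_trees")],
      gs_rev[[comp]][c("tc", "lr", "bf", "n_trees")]
    )
  }
})

test_that("grid-search ties are broken by fewer trees", {
  trail <- tibble::tibble(
    cv_deviance_mean = c(1, 1), n_trees = c(500L, 300L),
    tc = c(2L, 2L), lr = c(0.01, 0.01), bf = c(0.5, 0.5)
  )
  key <- order(trail$cv_deviance_mean, trail$n_trees, trail$tc, trail$lr,
               trail$bf)
  expect_equal(key[1], 2L)
})

test_that("a single candidate combination is selected without comparison", {
  sys <- tiny_system()
  cfg <- brt_config(tc = 2, lr = 0.05, bf = 0.6, cv_folds = 3, seed = 5,
                    simplify = FALSE)
  gs <- suppressWarnings(grid_search(sys$samples, "cpue",
                                     attr(sys$samples, "expvars"), cfg))
  expect_equal(nrow(gs$trail), 2)
  expect_true(all(gs$trail$selected))
})

test_that("backward elimination drops a pure-noise variable and keeps a
           single-variable model unchanged", {
  dropped <- 0L
  kept_signal <- 0L
  n_seeds <- 10
  for (seed in seq_len(n_seeds)) {
    set.seed(seed)
    n <- 500
    X <- cbind(x1 = runif(n, -2, 2), x2 = runif(n, -2, 2),
               x3 = runif(n, -2, 2))
    y <- sin(2 * X[, "x1"]) + X[, "x2"] + rnorm(n, 0, 0.3)
    cfg <- brt_config(tc = 2, lr = 0.1, bf = 0.7, cv_folds = 3, seed = seed)
    fit <- suppressWarnings(
      fit_component(X, y, "gaussian", 2, 0.1, 0.7, cv_folds = 3,
                    seed = seed)
    )
    simp <- suppressWarnings(simplify_component(fit, cfg))
    if (!"x3" %in% simp$kept_expvars) dropped <- dropped + 1L
    if (all(c("x1", "x2") %in% simp$kept_expvars)) {
      kept_signal <- kept_signal + 1L
    }
  }
  expect_gte(dropped, 0.8 * n_seeds)
  expect_gte(kept_signal, 0.8 * n_seeds)

  # single-variable fits bypass elimination entirely
  set.seed(1)
  X1 <- cbind(x1 = runif(200, -2, 2))
  y1 <- X1[, "x1"] + rnorm(200, 0, 0.2)
  f1 <- suppressWarnings(fit_component(X1, y1, "gaussian", 2, 0.1, 0.7,
                                       cv_folds = 3, seed = 1))
  s1 <- simplify_component(f1, brt_config(cv_folds = 3, seed = 1))
  expect_identical(s1$kept_expvars, "x1")
})

test_that("elimination refuses to drop variables that are all essential", {
  set.seed(4)
  n <- 400
  X <- cbind(x1 = runif(n, -1, 1), x2 = runif(n, -1, 1))
  y <- X[, "x1"] + X[, "x2"]  # noise-free, both needed
  cfg <- brt_config(tc = 2, lr = 0.1, bf = 0.8, cv_folds = 3, seed = 4)
  fit <- suppressWarnings(fit_component(X, y, "gaussian", 2, 0.1, 0.8,
                                        cv_folds = 3, seed = 4))
  simp <- suppressWarnings(simplify_component(fit, cfg))
  expect_setequal(simp$kept_expvars, c("x1", "x2"))
  expect_equal(nrow(attr(simp, "simplify_trail")), 0)
})
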