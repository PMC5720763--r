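test_that("relative influence normalises to 100 and ranks signal over
           noise", {
  fit <- signal_noise_component(seed = 1)
  infl <- relative_influence(fit)
  expect_equal(sum(infl$influence), 100, tolerance = 1e-6)
  expect_true(all(infl$influence >= 0))

  # single-variable model: that variable carries everything
  set.seed(2)
  X1 <- cbind(x1 = runif(300, -2, 2))
  y1 <- X1[, "x1"] + rnorm(300, 0.2)
  f1 <- suppressWarnings(fit_component(X1, y1, "gaussian", 2, 0.1, 0.8,
                                       cv_folds = 3, seed = 2))
  expect_equal(relative_influence(f1)$influence, 100, tolerance = 1e-6)

  # y depends only on x1; x2 is pure noise: x1 wins across seeded runs
  n_runs <- 30
  wins <- 0L
  for (seed in seq_len(n_runs)) {
    fit_s <- signal_noise_component(seed = seed)
    tab <- relative_influence(fit_s)
    if (tab$influence[tab$variable == "x1"] >
        tab$influence[tab$variable == "x2"]) {
      wins <- wins + 1L
    }
  }
  expect_gte(wins, ceiling(0.95 * n_runs))
})

test_that("partial dependence tracks a monotone signal and is flat for an
           unused variable", {
  fit <- signal_noise_component(seed = 3, family = "bernoulli")
  pd <- partial_dependence(fit, "x1")
  expect_equal(nrow(pd), 100)
  expect_true(all(diff(pd$x) > 0))
  # monotone increasing signal: strong rank agreement with x
  expect_gte(cor(pd$x, pd$effect, method = "spearman"), 0.9)
  # endpoints stay inside the sampled range
  expect_gte(min(pd$x), min(fit$X[, "x1"]))
  expect_lte(max(pd$x), max(fit$X[, "x1"]))

  # a variable the ensemble never splits on gives a flat curve
  set.seed(4)
  X <- cbind(x1 = runif(400, -2, 2), x2 = runif(400, -2, 2))
  y <- 3 * X[, "x1"] + rnorm(400, 0, 0.05)
  f <- suppressWarnings(fit_component(X, y, "gaussian", 1, 0.2, 1,
                                      cv_folds = 3, seed = 4))
  imp <- relative_influence(f)
  if (imp$influence[imp$variable == "x2"] == 0) {
    pd2 <- partial_dependence(f, "x2")
    expect_lt(diff(range(pd2$effect)), 1e-9)
  }

  expect_error(partial_dependence(fit, "nope"), "not a model variable")
})

test_that("dot-plot contributions are centred, one point per row, and show
           no trend for a noise variable", {
  fit <- signal_noise_component(seed = 5)
  dd <- dotplot_data(fit, "x2")
  expect_equal(nrow(dd), nrow(fit$X))
  expect_lt(abs(mean(dd$contribution)), 1e-9)
  expect_lt(abs(cor(dd$x, dd$contribution, method = "spearman")), 0.1)
})

test_that("interaction strength is symmetric, near zero for additive
           truth, and largest for the truly interacting pair", {
  set.seed(6)
  n <- 600
  X <- cbind(x1 = runif(n, -1, 1), x2 = runif(n, -1, 1),
             x3 = runif(n, -1, 1))
  y_add <- X[, "x1"] + X[, "x2"]
  f_add <- suppressWarnings(fit_component(X, y_add, "gaussian", 2, 0.1, 0.8,
                                          cv_folds = 3, seed = 6))
  s_add <- interaction_strength(f_add, "x1", "x2")
  expect_lt(s_add, 0.01)
  expect_equal(s_add, interaction_strength(f_add, "x2", "x1"))

  y_mul <- X[, "x1"] * X[, "x2"] + rnorm(n, 0, 0.05)
  f_mul <- suppressWarnings(fit_component(X, y_mul, "gaussian", 3, 0.1, 0.8,
                                          cv_folds = 3, seed = 6))
  s_12 <- interaction_strength(f_mul, "x1", "x2")
  expect_gt(s_12, interaction_strength(f_mul, "x1", "x3"))
  expect_gt(s_12, interaction_strength(f_mul, "x2", "x3"))
})

test_that("the gaussian partial curve keeps its ranking through the
           response-scale transform", {
  fit <- tiny_fit()
  pd <- partial_dependence(fit$gaussian, "x1", n_points = 50)
  response <- fit$smearing_factor * exp(pd$effect)
  expect_equal(cor(pd$effect, response, method = "spearman"), 1)
})

test_that("the model report captures the search, influence and smearing and
           survives a CSV round-trip", {
  sys <- tiny_system()
  cfg <- brt_config(tc = c(1, 2), lr = c(0.05, 0.1), bf = 0.6,
                    cv_folds = 3, seed = 8, simplify = FALSE)
  fit <- suppressWarnings(delta_fit(sys$samples, "cpue", config = cfg))
  rep <- model_report(fit, n_interactions = 1)
  expect_equal(sum(rep$section == "search" & rep$component == "binary"), 4)
  expect_equal(sum(rep$section == "search" & rep$component == "gaussian"), 4)
  expect_true("smearing_factor" %in% rep$name)
  expect_true(any(rep$section == "influence"))

  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(rep, path)
  back <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(.default = "c"))
  expect_equal(as.data.frame(back),
               as.data.frame(dplyr::mutate(rep,
                                           dplyr::across(dplyr::everything(),
                                                         as.character))))
})

test_that("a simplification run records the dropped-variable trail in the
           report", {
  set.seed(9)
  sys <- tiny_system()
  cfg <- brt_config(tc = 2, lr = 0.1, bf = 0.7, cv_folds = 3, seed = 9,
                    simplify = TRUE)
  fit <- suppressWarnings(delta_fit(sys$samples, "cpue", config = cfg))
  rep <- model_report(fit, n_interactions = 0)
  n_dropped <- sum(vapply(fit$simplify_trail, function(t) {
    if (is.null(t)) 0L else nrow(t)
  }, integer(1)))
  expect_equal(sum(rep$section == "simplification"), n_dropped)
})
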