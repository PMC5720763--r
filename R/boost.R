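# Boosted-tree component fitting. The ensemble itself is standard gradient
# boosting (xgboost); what is bespoke here is the cross-validated stopping
# rule: trees are grown in blocks of `block_size`, mean k-fold held-out
# deviance is evaluated after each block, and growth stops once the curve has
# not improved for `patience` consecutive blocks (or at `max_trees`). The
# selected tree count is the argmin of the block-level CV deviance curve.

# Held-out deviance on the response scale, per family. Stated explicitly so
# CV comparisons across hyperparameter combinations are well defined:
# bernoulli = -2 * mean Bernoulli log-likelihood, gaussian = mean squared
# error, poisson = mean unit deviance.
component_deviance <- function(y, mu, family) {
  switch(family,
    bernoulli = {
      p <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
      -2 * mean(y * log(p) + (1 - y) * log(1 - p))
    },
    gaussian = mean((y - mu)^2),
    poisson = {
      mu <- pmax(mu, 1e-12)
      2 * mean(mu - y + ifelse(y > 0, y * log(y / mu), 0))
    },
    abort(paste0("unknown family: ", family))
  )
}

null_deviance <- function(y, family) {
  mu <- switch(family, bernoulli = mean(y), gaussian = mean(y),
               poisson = mean(y))
  component_deviance(y, rep(mu, length(y)), family)
}

xgb_objective <- function(family) {
  switch(family,
    bernoulli = "binary:logistic",
    gaussian = "reg:squarederror",
    poisson = "count:poisson",
    abort(paste0("unknown family: ", family))
  )
}

# Fold assignment derived from the seed; stratified on the response for the
# occurrence component so every fold sees both classes.
make_folds <- function(y, k, seed, stratify = FALSE) {
  n <- length(y)
  with_seed(seed, {
    if (stratify) {
      folds <- integer(n)
      for (cls in unique(y)) {
        idx <- which(y == cls)
        folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
      folds
    } else {
      sample(rep_len(seq_len(k), n))
    }
  })
}

xgb_params <- function(family, tc, lr, bf, seed) {
  list(
    objective = xgb_objective(family),
    max_depth = as.integer(tc),
    eta = lr,
    subsample = bf,
    tree_method = "exact",
    nthread = 1,
    seed = as.integer(seed)
  )
}

# Wilcoxon-statistic AUC; ties get half credit.
auc_score <- function(y, p) {
  pos <- p[y == 1]
  neg <- p[y == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Fit one boosted-tree component with cross-validated early stopping
#'
#' Fits a single gradient-boosted tree ensemble (the occurrence or the
#' positive-abundance half of the delta model, or a standalone single-family
#' model). Trees are grown in blocks of `block_size`; after each block the
#' mean k-fold held-out deviance is computed, and growth stops when the curve
#' has not improved for `patience` consecutive blocks or `max_trees` is
#' reached. The returned tree count is the argmin of the CV deviance curve,
#' and the final ensemble is refitted on all rows at that size.
#'
#' @param X Numeric matrix of explanatory variables (named columns). `NA`
#'   entries are allowed; the tree learner routes them via default directions.
#' @param y Response vector: 0/1 for `bernoulli`, real for `gaussian`,
#'   non-negative integer for `poisson`.
#' @param family One of `"bernoulli"`, `"gaussian"`, `"poisson"`.
#' @param tc Tree complexity (interaction depth), a positive integer.
#' @param lr Learning rate (shrinkage), positive.
#' @param bf Bag fraction in (0, 1]: the share of rows subsampled per tree.
#' @param cv_folds Number of CV folds (stratified on `y` for bernoulli).
#' @param seed Integer seed controlling folds and subsampling.
#' @param block_size,patience,max_trees Stopping rule: block growth size,
#'   number of non-improving blocks tolerated, and the tree cap.
#' @return A `brt_component` object: family, hyperparameters, `n_trees`,
#'   `cv_deviance_mean` and `cv_deviance_se` at the curve minimum, the full
#'   `cv_curve`, `train_metric` (training AUC for bernoulli, pseudo-R^2
#'   otherwise), `kept_expvars`, and the fitted ensemble.
#' @export
fit_component <- function(X, y, family, tc, lr, bf, cv_folds = 10, seed = 1,
                          block_size = 50, patience = 2, max_trees = 10000) {
  stopifnot(is.matrix(X), !is.null(colnames(X)), nrow(X) == length(y))
  if (family == "bernoulli") {
    n_pos <- sum(y == 1)
    n_neg <- sum(y == 0)
    if (n_pos < cv_folds || n_neg < cv_folds) {
      abort(paste0(
        "cannot stratify ", cv_folds, "-fold CV: only ", n_pos,
        " positive and ", n_neg, " negative cases"
      ))
    }
  }
  degenerate <- var(y) == 0
  folds <- make_folds(y, cv_folds, seed, stratify = family == "bernoulli")
  params <- xgb_params(family, tc, lr, bf, seed)

  fold_sets <- lapply(seq_len(cv_folds), function(f) {
    train <- folds != f
    list(
      dtrain = xgboost::xgb.DMatrix(X[train, , drop = FALSE],
                                    label = y[train], nthread = 1),
      y_test = y[!train],
      X_test = X[!train, , drop = FALSE],
      booster = NULL
    )
  })

  max_blocks <- ceiling(max_trees / block_size)
  dev_mat <- matrix(NA_real_, nrow = max_blocks, ncol = cv_folds)
  n_blocks <- 0L
  for (b in seq_len(max_blocks)) {
    for (f in seq_len(cv_folds)) {
      fs <- fold_sets[[f]]
      fs$booster <- xgboost::xgb.train(
        params = params, data = fs$dtrain, nrounds = block_size,
        verbose = 0, xgb_model = fs$booster
      )
      mu <- predict(fs$booster, fs$X_test)
      dev_mat[b, f] <- component_deviance(fs$y_test, mu, family)
      fold_sets[[f]] <- fs
    }
    n_blocks <- b
    best <- which.min(rowMeans(dev_mat[seq_len(b), , drop = FALSE]))
    if (b - best >= patience) break
  }
  dev_mat <- dev_mat[seq_len(n_blocks), , drop = FALSE]
  cv_mean <- rowMeans(dev_mat)
  cv_se <- apply(dev_mat, 1, sd) / sqrt(cv_folds)
  best_block <- which.min(cv_mean)
  if (best_block == 1L && n_blocks > 1L) {
    warn(paste0("CV deviance is minimal at the first ", block_size,
                " trees: lr = ", lr, " may be too high"))
  }
  n_trees <- best_block * block_size

  dall <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  booster <- xgboost::xgb.train(params = params, data = dall,
                                nrounds = n_trees, verbose = 0)
  mu_train <- predict(booster, X)
  train_metric <- if (family == "bernoulli") {
    auc_score(y, mu_train)
  } else if (degenerate) {
    NA_real_
  } else {
    1 - component_deviance(y, mu_train, family) / null_deviance(y, family)
  }

  structure(
    list(
      family = family, tc = as.integer(tc), lr = lr, bf = bf,
      n_trees = as.integer(n_trees),
      cv_deviance_mean = cv_mean[best_block],
      cv_deviance_se = cv_se[best_block],
      cv_curve = tibble(
        block = seq_len(n_blocks), n_trees = seq_len(n_blocks) * block_size,
        cv_deviance_mean = cv_mean, cv_deviance_se = cv_se
      ),
      train_metric = train_metric,
      kept_expvars = colnames(X),
      degenerate = degenerate,
      booster = booster,
      X = X, y = y,
      cv_folds = as.integer(cv_folds), seed = as.integer(seed),
      block_size = as.integer(block_size), patience = as.integer(patience),
      max_trees = as.integer(max_trees)
    ),
    class = "brt_component"
  )
}

#' @export
print.brt_component <- function(x, ...) {
  cat("<brt_component> family:", x$family,
      " tc:", x$tc, " lr:", x$lr, " bf:", x$bf, "\n",
      " trees:", x$n_trees,
      " CV deviance:", signif(x$cv_deviance_mean, 5),
      "+/-", signif(x$cv_deviance_se, 3), "\n",
      " train metric:", signif(x$train_metric, 4),
      " variables:", paste(x$kept_expvars, collapse = ", "), "\n")
  invisible(x)
}

# Link-scale (margin) predictions of a component on new rows.
component_link <- function(fit, X) {
  predict(fit$booster, X[, fit$kept_expvars, drop = FALSE],
          outputmargin = TRUE)
}

# Response-scale predictions.
component_response <- function(fit, X) {
  predict(fit$booster, X[, fit$kept_expvars, drop = FALSE])
}
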