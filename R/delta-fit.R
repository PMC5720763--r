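#' Configuration for a delta BRT run
#'
#' Collects the hyperparameter candidate lists and run options of a delta
#' log-normal boosted-regression-tree fit. The search loops bag fraction
#' nested within learning rate nested within tree complexity and keeps the
#' combination with minimal cross-validated deviance.
#'
#' @param tc Tree complexity (interaction depth) candidates, positive
#'   integers.
#' @param lr Learning rate candidates, positive reals.
#' @param bf Bag fraction candidates in (0, 1].
#' @param family_binary Distribution of the occurrence component.
#' @param family_gaussian Distribution of the positive-abundance component.
#' @param zi Zero inflation: `TRUE` forces the delta pathway, `FALSE` a
#'   single-family run, `"auto"` decides from the observed share of zeros.
#' @param zi_threshold Proportion of exact zeros that triggers the delta
#'   pathway under `zi = "auto"` (default 0.5).
#' @param family_single Family of the single-component run when the delta
#'   pathway is not used (`"gaussian"` or `"poisson"`).
#' @param simplify Run backward elimination on the selected fits?
#' @param cv_folds Cross-validation folds (>= 2, default 10).
#' @param seed Integer seed for folds and subsampling.
#' @param block_size,patience,max_trees Early-stopping rule of
#'   [fit_component()].
#' @param min_train_rows Smallest per-iteration training subsample accepted;
#'   combinations whose `bf` is infeasible per [bfcheck()] are refused.
#' @return A `brt_config` list.
#' @export
brt_config <- function(tc = 2, lr = 0.01, bf = 0.5,
                       family_binary = "bernoulli",
                       family_gaussian = "gaussian",
                       zi = "auto", zi_threshold = 0.5,
                       family_single = "gaussian",
                       simplify = TRUE, cv_folds = 10, seed = 1,
                       block_size = 50, patience = 2, max_trees = 10000,
                       min_train_rows = 21) {
  stopifnot(
    length(tc) >= 1, all(tc >= 1), all(tc == as.integer(tc)),
    length(lr) >= 1, all(lr > 0),
    length(bf) >= 1, all(bf > 0), all(bf <= 1),
    cv_folds >= 2,
    isTRUE(zi) || isFALSE(zi) || identical(zi, "auto"),
    zi_threshold > 0, zi_threshold <= 1,
    family_single %in% c("gaussian", "poisson")
  )
  structure(
    list(
      tc = as.integer(tc), lr = lr, bf = bf,
      family_binary = family_binary, family_gaussian = family_gaussian,
      zi = zi, zi_threshold = zi_threshold, family_single = family_single,
      simplify = simplify, cv_folds = as.integer(cv_folds),
      seed = as.integer(seed), block_size = as.integer(block_size),
      patience = as.integer(patience), max_trees = as.integer(max_trees),
      min_train_rows = as.integer(min_train_rows)
    ),
    class = "brt_config"
  )
}

# Fit every (tc, lr, bf) combination for one component and pick the winner:
# minimal CV deviance, ties broken by fewer trees, then lower tc, lower lr,
# lower bf — a total order, so the choice cannot depend on candidate-list
# ordering.
search_component <- function(X, y, family, config) {
  combos <- expand.grid(bf = config$bf, lr = config$lr, tc = config$tc,
                        KEEP.OUT.ATTRS = FALSE)
  fits <- vector("list", nrow(combos))
  failures <- character(0)
  for (i in seq_len(nrow(combos))) {
    cm <- combos[i, ]
    fits[[i]] <- tryCatch(
      fit_component(X, y, family,
                    tc = cm$tc, lr = cm$lr, bf = cm$bf,
                    cv_folds = config$cv_folds, seed = config$seed,
                    block_size = config$block_size,
                    patience = config$patience,
                    max_trees = config$max_trees),
      error = function(e) {
        failures <<- c(failures, paste0("tc=", cm$tc, " lr=", cm$lr,
                                        " bf=", cm$bf, ": ",
                                        conditionMessage(e)))
        NULL
      }
    )
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) {
    abort(paste0("every hyperparameter combination failed:\n  ",
                 paste(failures, collapse = "\n  ")))
  }
  trail <- purrr::map(fits[ok], function(f) {
    tibble(tc = f$tc, lr = f$lr, bf = f$bf, n_trees = f$n_trees,
           cv_deviance_mean = f$cv_deviance_mean,
           cv_deviance_se = f$cv_deviance_se,
           train_metric = f$train_metric)
  }) |> list_rbind()
  keep <- fits[ok]
  key <- order(trail$cv_deviance_mean, trail$n_trees, trail$tc, trail$lr,
               trail$bf)
  best <- keep[[key[1]]]
  trail$selected <- seq_len(nrow(trail)) == key[1]
  list(best = best, trail = arrange(trail, .data$tc, .data$lr, .data$bf),
       failures = failures)
}

#' Hyperparameter grid search for the two delta components
#'
#' Fits every `(tc, lr, bf)` combination of `config` for the occurrence
#' (binary) and the positive-abundance (log-Gaussian) component and selects,
#' per component, the combination with minimal cross-validated deviance (ties
#' broken by fewer trees, then lower `tc`, then lower `lr`).
#'
#' @param samples A samples tibble.
#' @param resvar Response variable name.
#' @param expvars Explanatory variable names.
#' @param config A [brt_config()].
#' @return A list with elements `binary` and `gaussian` (the selected
#'   `brt_component` fits) and `trail` (a tibble of every combination's CV
#'   metrics per component).
#' @export
grid_search <- function(samples, resvar, expvars, config = brt_config()) {
  parts <- split_binary_gaussian(samples, resvar)
  Xb <- as.matrix(samples[, expvars, drop = FALSE])
  Xg <- as.matrix(parts$positive[, expvars, drop = FALSE])
  res_b <- search_component(Xb, parts$binary, config$family_binary, config)
  res_g <- search_component(Xg, parts$positive[[resvar]],
                            config$family_gaussian, config)
  list(
    binary = res_b$best, gaussian = res_g$best,
    trail = bind_rows(
      mutate(res_b$trail, component = "binary", .before = 1),
      mutate(res_g$trail, component = "gaussian", .before = 1)
    )
  )
}

#' Backward-eliminate explanatory variables from a fitted component
#'
#' Tests whether the component performs as well with variables omitted:
#' repeatedly refits without each remaining variable, removes the one whose
#' absence least increases the cross-validated deviance, and stops when even
#' the best candidate removal worsens CV deviance by more than one fold
#' standard error of the current model (the 1-SE rule). Fits with a single
#' variable are returned unchanged.
#'
#' @param fit A `brt_component`.
#' @param config The run's [brt_config()].
#' @return A `brt_component` (possibly the input) with attribute
#'   `simplify_trail`: a tibble of dropped variables and their CV deviance
#'   increments.
#' @export
simplify_component <- function(fit, config = brt_config()) {
  trail <- tibble(dropped = character(0), delta_cv_deviance = numeric(0))
  current <- fit
  while (length(current$kept_expvars) >= 2) {
    cand <- purrr::map(current$kept_expvars, function(v) {
      keep <- setdiff(current$kept_expvars, v)
      f <- fit_component(current$X[, keep, drop = FALSE], current$y,
                         current$family, tc = current$tc, lr = current$lr,
                         bf = current$bf, cv_folds = config$cv_folds,
                         seed = config$seed, block_size = config$block_size,
                         patience = config$patience,
                         max_trees = config$max_trees)
      list(var = v, fit = f)
    })
    devs <- map_dbl(cand, function(cc) cc$fit$cv_deviance_mean)
    best <- which.min(devs)
    delta <- devs[best] - current$cv_deviance_mean
    if (devs[best] > current$cv_deviance_mean + current$cv_deviance_se) {
      break
    }
    trail <- bind_rows(trail, tibble(dropped = cand[[best]]$var,
                                     delta_cv_deviance = delta))
    current <- cand[[best]]$fit
  }
  attr(current, "simplify_trail") <- trail
  current
}

#' Duan's smearing estimator
#'
#' Nonparametric retransformation factor for predictions of a model fitted on
#' the natural-log scale: the mean of the exponentiated log-scale training
#' residuals. Multiplying `exp(log-prediction)` by this factor corrects the
#' downward bias of naive exponentiation (for exactly normal residuals it
#' estimates `exp(sigma^2 / 2)`).
#'
#' @param log_residuals Residuals (observed minus fitted) on the log scale.
#' @return The smearing factor, a real `>= 0`.
#' @export
smearing_factor <- function(log_residuals) {
  if (length(log_residuals) == 0) abort("no residuals: cannot smear")
  mean(exp(log_residuals))
}

#' Fit a delta log-normal boosted regression tree model
#'
#' The main modelling entry point. When the response is zero inflated (forced
#' via `config$zi` or decided automatically from the share of exact zeros),
#' two boosted ensembles are fitted: occurrence (all rows, presence/absence)
#' and positive abundance (positive rows, natural-log response). Each is
#' selected over the `(tc, lr, bf)` grid by cross-validated deviance and
#' optionally simplified by backward elimination; the log-scale fit's
#' retransformation bias is corrected with Duan's smearing estimator. When
#' the response is not zero inflated a single ensemble of
#' `config$family_single` is fitted instead.
#'
#' @param samples A samples tibble (see [read_samples()] / [as_samples()]).
#' @param resvar Response variable name.
#' @param expvars Explanatory variable names (default: the table's recorded
#'   set).
#' @param config A [brt_config()].
#' @param grids Optional grid tibble; when supplied, predictions are computed
#'   immediately and stored in the result's `predictions`.
#' @return A `delta_fit` object: components `binary` and `gaussian` (either
#'   may be `NULL` on the single-family path), `smearing_factor` (delta path
#'   only), `zi_used`, the search `trail`, simplification trails, `config`,
#'   and `predictions` when `grids` was given.
#' @export
delta_fit <- function(samples, resvar, expvars = attr(samples, "expvars"),
                      config = brt_config(), grids = NULL) {
  if (is.null(expvars)) abort("expvars must be given")
  if (!resvar %in% names(samples)) {
    abort(paste0("response '", resvar, "' not found"))
  }
  if (!is.null(grids)) validate_match(samples, grids, expvars)
  y <- samples[[resvar]]
  if (any(y < 0)) abort("response must be non-negative")

  zi_used <- if (identical(config$zi, "auto")) {
    check_zero_inflation(y, config$zi_threshold)
  } else {
    isTRUE(config$zi)
  }

  feas <- bfcheck(samples, resvar, config$min_train_rows)
  binary <- gaussian <- NULL
  smear <- NULL
  trail <- NULL

  if (zi_used) {
    bad_bf <- config$bf[vapply(config$bf, function(b) {
      floor(b * feas$n[feas$component == "gaussian"] + 1e-9) <
        config$min_train_rows ||
        floor(b * feas$n[feas$component == "binary"] + 1e-9) <
          config$min_train_rows
    }, logical(1))]
    if (length(bad_bf) == length(config$bf)) {
      abort("every candidate bag fraction is infeasible; see bfcheck()")
    }
    if (length(bad_bf) > 0) {
      warn(paste0("dropping infeasible bag fraction(s): ",
                  paste(bad_bf, collapse = ", ")))
      config$bf <- setdiff(config$bf, bad_bf)
    }
    gs <- grid_search(samples, resvar, expvars, config)
    binary <- gs$binary
    gaussian <- gs$gaussian
    trail <- gs$trail
    if (config$simplify) {
      if (length(binary$kept_expvars) >= 2) {
        binary <- simplify_component(binary, config)
      }
      if (length(gaussian$kept_expvars) >= 2) {
        gaussian <- simplify_component(gaussian, config)
      }
    }
    smear <- smearing_factor(gaussian$y - component_link(gaussian,
                                                         gaussian$X))
  } else {
    X <- as.matrix(samples[, expvars, drop = FALSE])
    res <- search_component(X, y, config$family_single, config)
    gaussian <- res$best
    trail <- mutate(res$trail, component = config$family_single, .before = 1)
    if (config$simplify && length(gaussian$kept_expvars) >= 2) {
      gaussian <- simplify_component(gaussian, config)
    }
  }

  fit <- structure(
    list(
      binary = binary, gaussian = gaussian,
      smearing_factor = smear, zi_used = zi_used,
      resvar_name = resvar, expvars = expvars,
      config = config, seed = config$seed,
      trail = trail,
      simplify_trail = list(
        binary = attr(binary, "simplify_trail"),
        gaussian = attr(gaussian, "simplify_trail")
      ),
      n_samples = nrow(samples)
    ),
    class = "delta_fit"
  )
  if (!is.null(grids)) fit$predictions <- predict(fit, grids)
  fit
}

#' @export
print.delta_fit <- function(x, ...) {
  cat("<delta_fit> response:", x$resvar_name,
      if (x$zi_used) "(delta log-normal)" else "(single family)", "\n")
  if (!is.null(x$binary)) {
    cat(" occurrence : tc", x$binary$tc, "lr", x$binary$lr,
        "bf", x$binary$bf, "trees", x$binary$n_trees,
        "AUC", signif(x$binary$train_metric, 3), "\n")
  }
  if (!is.null(x$gaussian)) {
    cat(" abundance  : tc", x$gaussian$tc, "lr", x$gaussian$lr,
        "bf", x$gaussian$bf, "trees", x$gaussian$n_trees,
        "pseudo-R2", signif(x$gaussian$train_metric, 3), "\n")
  }
  if (!is.null(x$smearing_factor)) {
    cat(" smearing factor:", signif(x$smearing_factor, 5), "\n")
  }
  invisible(x)
}

#' Predict a combined abundance surface on a grid
#'
#' Applies the fitted delta model to a grid table: the occurrence component
#' yields a probability per cell, the positive-abundance component a
#' log-scale prediction that is exponentiated and multiplied by the smearing
#' factor, and the combined abundance index is their product. Cells with a
#' missing value in any explanatory variable used by either component get
#' missing predictions. On the single-family path the component's
#' response-scale prediction is the combined index and `p_occurrence` is
#' reported as 1.
#'
#' @param object A `delta_fit`.
#' @param grids A grid tibble with the model's explanatory variables.
#' @param ... Unused.
#' @return A `prediction_surface` tibble: `latitude`, `longitude`,
#'   `p_occurrence`, `positive_abundance`, `combined_index`.
#' @export
predict.delta_fit <- function(object, grids, ...) {
  used <- unique(c(
    if (!is.null(object$binary)) object$binary$kept_expvars,
    if (!is.null(object$gaussian)) object$gaussian$kept_expvars
  ))
  missing_cols <- setdiff(used, names(grids))
  if (length(missing_cols) > 0) {
    abort(paste0("grids table lacks model variable(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  X <- as.matrix(grids[, used, drop = FALSE])
  bad <- rowSums(is.na(X)) > 0

  if (object$zi_used) {
    p <- component_response(object$binary, X)
    mu_log <- component_link(object$gaussian, X)
    abundance <- object$smearing_factor * exp(mu_log)
  } else {
    p <- rep(1, nrow(X))
    abundance <- component_response(object$gaussian, X)
  }
  p[bad] <- NA_real_
  abundance[bad] <- NA_real_
  out <- tibble(
    latitude = grids$latitude, longitude = grids$longitude,
    p_occurrence = p, positive_abundance = abundance,
    combined_index = p * abundance
  )
  class(out) <- c("prediction_surface", class(out))
  out
}

delta_model_schema <- 1L

#' Save / load a fitted delta model
#'
#' `write_delta_model()` serialises a `delta_fit` (boosted ensembles included,
#' as raw engine bytes) with a schema version; `read_delta_model()` restores
#' it, refusing files written under a newer schema and reporting corrupt
#' files explicitly. Predictions of a restored model are bit-identical to the
#' original's.
#'
#' @param model A `delta_fit`.
#' @param path File path (`.rds`).
#' @return `write_delta_model()` the path, invisibly; `read_delta_model()` the
#'   restored `delta_fit`.
#' @export
write_delta_model <- function(model, path) {
  stopifnot(inherits(model, "delta_fit"))
  pack <- function(comp) {
    if (is.null(comp)) return(NULL)
    comp$booster_raw <- xgboost::xgb.save.raw(comp$booster)
    comp$booster <- NULL
    comp
  }
  payload <- model
  payload$binary <- pack(model$binary)
  payload$gaussian <- pack(model$gaussian)
  saveRDS(list(schema = delta_model_schema, model = payload), path)
  invisible(path)
}

#' @rdname write_delta_model
#' @export
read_delta_model <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    abort(paste0("cannot read model file '", path, "': ",
                 conditionMessage(e)))
  })
  if (!is.list(obj) || is.null(obj$schema) || is.null(obj$model)) {
    abort(paste0("'", path, "' is not a delta model file"))
  }
  if (obj$schema > delta_model_schema) {
    abort(paste0("model file schema version ", obj$schema,
                 " is newer than the supported version ",
                 delta_model_schema))
  }
  unpack <- function(comp) {
    if (is.null(comp)) return(NULL)
    comp$booster <- xgboost::xgb.load.raw(comp$booster_raw)
    comp$booster_raw <- NULL
    comp
  }
  model <- obj$model
  model$binary <- unpack(model$binary)
  model$gaussian <- unpack(model$gaussian)
  model
}
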