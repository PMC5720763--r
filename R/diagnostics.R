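# Model interrogation: relative influence, partial dependence, per-row
# fitted-contribution dot plots, two-way interaction strength, and the
# consolidated run report. All quantities are computed on the link scale;
# response-scale rendering is a plotting option.

#' Relative influence of explanatory variables
#'
#' Attributes the ensemble's total loss reduction to each variable (summed
#' over every split using it) and normalises to percentages summing to 100.
#' Variables kept by the model but never used by any split get 0.
#'
#' @param fit A `brt_component`.
#' @return An `influence_table` tibble: `variable`, `influence` (percent).
#'   A degenerate (constant) fit returns all zeros with attribute
#'   `degenerate = TRUE` and a warning.
#' @export
relative_influence <- function(fit) {
  stopifnot(inherits(fit, "brt_component"))
  tree <- xgboost::xgb.model.dt.tree(model = fit$booster)
  splits <- tree[tree$Feature != "Leaf", c("Feature", "Gain")]
  out <- tibble(variable = fit$kept_expvars, influence = 0)
  if (nrow(splits) == 0 || fit$degenerate) {
    warn("degenerate fit: no splits were made, influence is undefined")
    attr(out, "degenerate") <- TRUE
  } else {
    gain <- tapply(splits$Gain, splits$Feature, sum)
    idx <- match(names(gain), out$variable)
    out$influence[idx] <- 100 * as.numeric(gain) / sum(gain)
  }
  class(out) <- c("influence_table", class(out))
  out
}

# Mean link-scale prediction over the training rows with `cols` clamped to
# the given values (a row of `at` per evaluation point).
pd_average <- function(fit, at) {
  n <- nrow(fit$X)
  vapply(seq_len(nrow(at)), function(i) {
    X <- fit$X
    for (v in names(at)) X[, v] <- at[[v]][i]
    mean(component_link(fit, X))
  }, numeric(1))
}

#' Partial dependence of a fitted component on one variable
#'
#' The marginal effect curve: for each of `n_points` evenly spaced values
#' spanning the variable's sampled range, the average link-scale prediction
#' over all training rows with the variable clamped to that value.
#'
#' @param fit A `brt_component`.
#' @param variable Name of a kept explanatory variable.
#' @param n_points Number of evaluation points (default 100).
#' @return A `partial_curve` tibble: `variable`, `x`, `effect`.
#' @export
partial_dependence <- function(fit, variable, n_points = 100) {
  stopifnot(inherits(fit, "brt_component"))
  if (!variable %in% fit$kept_expvars) {
    abort(paste0("'", variable, "' is not a model variable"))
  }
  r <- range(fit$X[, variable], na.rm = TRUE)
  xs <- seq(r[1], r[2], length.out = n_points)
  out <- tibble(
    variable = variable, x = xs,
    effect = pd_average(fit, stats::setNames(tibble(xs), variable))
  )
  class(out) <- c("partial_curve", class(out))
  out
}

#' Per-observation fitted contributions against one variable
#'
#' The dot-plot companion of [partial_dependence()]: for every training row,
#' its full link-scale prediction (all variables at their observed values)
#' centred on the component's mean prediction, paired with the row's value of
#' `variable`. The spread at a given x shows how much the other variables
#' modulate the effect.
#'
#' @inheritParams partial_dependence
#' @return A tibble with one row per training observation: `x`,
#'   `contribution` (centred link-scale fit).
#' @export
dotplot_data <- function(fit, variable) {
  stopifnot(inherits(fit, "brt_component"))
  if (!variable %in% fit$kept_expvars) {
    abort(paste0("'", variable, "' is not a model variable"))
  }
  pred <- component_link(fit, fit$X)
  tibble(x = fit$X[, variable], contribution = pred - mean(pred))
}

#' Two-way interaction strength of a variable pair
#'
#' Evaluates the two-way partial-dependence surface on an `n_grid` x `n_grid`
#' lattice over the two variables' sampled ranges, removes the additive
#' row/column structure (row means + column means - grand mean), and returns
#' the mean squared residual. A purely additive pair scores 0; larger values
#' indicate the ensemble uses the pair jointly.
#'
#' @param fit A `brt_component`.
#' @param var_a,var_b Names of two kept explanatory variables.
#' @param n_grid Lattice resolution per axis (default 20).
#' @return A non-negative scalar, symmetric in its arguments.
#' @export
interaction_strength <- function(fit, var_a, var_b, n_grid = 20) {
  stopifnot(inherits(fit, "brt_component"))
  for (v in c(var_a, var_b)) {
    if (!v %in% fit$kept_expvars) {
      abort(paste0("'", v, "' is not a model variable"))
    }
  }
  ra <- range(fit$X[, var_a], na.rm = TRUE)
  rb <- range(fit$X[, var_b], na.rm = TRUE)
  xa <- seq(ra[1], ra[2], length.out = n_grid)
  xb <- seq(rb[1], rb[2], length.out = n_grid)
  at <- expand.grid(a = xa, b = xb, KEEP.OUT.ATTRS = FALSE)
  names(at) <- c(var_a, var_b)
  f <- matrix(pd_average(fit, at), nrow = n_grid)
  resid <- f - outer(rowMeans(f), colMeans(f), "+") + mean(f)
  mean(resid^2)
}

#' Consolidated model report
#'
#' Collects everything needed to audit a run into one long-format table:
#' every hyperparameter combination's CV deviance and tree count, the
#' selected combinations, the simplification trail, per-variable influence,
#' the strongest interaction pairs, training metrics, the smearing factor,
#' the zero-inflation decision and the seed. Written as CSV it round-trips
#' losslessly.
#'
#' @param fit A `delta_fit`.
#' @param n_interactions Number of top interaction pairs to include per
#'   component (default 3; 0 skips the computation).
#' @return A tibble with columns `section`, `component`, `name`, `value`.
#' @export
model_report <- function(fit, n_interactions = 3) {
  stopifnot(inherits(fit, "delta_fit"))
  rows <- list()
  add <- function(section, component, name, value) {
    rows[[length(rows) + 1]] <<- tibble(
      section = section, component = component,
      name = name, value = as.character(value)
    )
  }
  add("run", "all", "resvar", fit$resvar_name)
  add("run", "all", "zero_inflated", fit$zi_used)
  add("run", "all", "seed", fit$seed)
  add("run", "all", "n_samples", fit$n_samples)
  if (!is.null(fit$smearing_factor)) {
    add("run", "all", "smearing_factor", format(fit$smearing_factor,
                                                digits = 17))
  }
  for (i in seq_len(nrow(fit$trail))) {
    tr <- fit$trail[i, ]
    add("search", tr$component,
        paste0("tc=", tr$tc, ";lr=", tr$lr, ";bf=", tr$bf),
        paste0("cv_dev=", format(tr$cv_deviance_mean, digits = 10),
               ";cv_se=", format(tr$cv_deviance_se, digits = 10),
               ";n_trees=", tr$n_trees,
               ";selected=", tr$selected))
  }
  comps <- purrr::compact(list(binary = fit$binary, gaussian = fit$gaussian))
  for (nm in names(comps)) {
    comp <- comps[[nm]]
    add("selected", nm, "hyperparameters",
        paste0("tc=", comp$tc, ";lr=", comp$lr, ";bf=", comp$bf,
               ";n_trees=", comp$n_trees))
    add("selected", nm, "cv_deviance",
        paste0(format(comp$cv_deviance_mean, digits = 10), " +/- ",
               format(comp$cv_deviance_se, digits = 10)))
    add("selected", nm,
        if (comp$family == "bernoulli") "train_auc" else "cv_pseudo_r2",
        format(comp$train_metric, digits = 10))
    st <- fit$simplify_trail[[nm]]
    if (!is.null(st) && nrow(st) > 0) {
      for (j in seq_len(nrow(st))) {
        add("simplification", nm, st$dropped[j],
            paste0("+", format(st$delta_cv_deviance[j], digits = 6)))
      }
    }
    infl <- suppressWarnings(relative_influence(comp))
    for (j in seq_len(nrow(infl))) {
      add("influence", nm, infl$variable[j],
          format(infl$influence[j], digits = 10))
    }
    if (n_interactions > 0 && length(comp$kept_expvars) >= 2) {
      pairs <- utils::combn(comp$kept_expvars, 2, simplify = FALSE)
      strength <- map_dbl(pairs, function(p) {
        interaction_strength(comp, p[1], p[2])
      })
      top <- order(strength, decreasing = TRUE)
      top <- top[seq_len(min(n_interactions, length(top)))]
      for (j in top) {
        add("interaction", nm, paste(pairs[[j]], collapse = ":"),
            format(strength[j], digits = 10))
      }
    }
  }
  list_rbind(rows)
}
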