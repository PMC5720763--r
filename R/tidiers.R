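#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted delta model
#'
#' One row per component x explanatory variable with the relative influence,
#' in broom style.
#'
#' @param x A `delta_fit`.
#' @param ... Unused.
#' @return A tibble: `component`, `variable`, `influence`.
#' @method tidy delta_fit
#' @export
tidy.delta_fit <- function(x, ...) {
  comps <- purrr::compact(list(binary = x$binary, gaussian = x$gaussian))
  purrr::imap(comps, function(comp, nm) {
    mutate(suppressWarnings(relative_influence(comp)),
           component = nm, .before = 1)
  }) |> list_rbind()
}

#' One-row summary of a fitted delta model
#'
#' @param x A `delta_fit`.
#' @param ... Unused.
#' @return A one-row tibble of run-level and per-component headline metrics.
#' @method glance delta_fit
#' @export
glance.delta_fit <- function(x, ...) {
  comp_cols <- function(comp, prefix) {
    if (is.null(comp)) return(tibble(.rows = 1))
    out <- tibble(
      tc = comp$tc, lr = comp$lr, bf = comp$bf, n_trees = comp$n_trees,
      cv_deviance = comp$cv_deviance_mean, metric = comp$train_metric
    )
    stats::setNames(out, paste0(prefix, "_", names(out)))
  }
  bind_cols(
    tibble(
      resvar = x$resvar_name, zi_used = x$zi_used,
      n_samples = x$n_samples,
      smearing_factor = x$smearing_factor %||% NA_real_,
      seed = x$seed
    ),
    comp_cols(x$binary, "binary"),
    comp_cols(x$gaussian, "gaussian")
  )
}

#' @method autoplot prediction_surface
#' @export
autoplot.prediction_surface <- function(object, value = "combined_index",
                                        ...) {
  render_map(object, value = value, legend = value, ...)
}

#' @method autoplot rsb_surface
#' @export
autoplot.rsb_surface <- function(object, value = "total", ...) {
  render_map(object, value = value, legend = "RSB score", ...)
}

#' @method autoplot conservation_surface
#' @export
autoplot.conservation_surface <- function(object, value = "total", ...) {
  render_map(object, value = value, legend = "conservation value", ...)
}

#' @method autoplot loop_summary
#' @export
autoplot.loop_summary <- function(object, ...) {
  render_map(object$cv, value = "cv", legend = "CV of prediction", ...)
}

#' Map a multi-species closure plan
#'
#' The classic multi-colour MPA map: member cells coloured by the species
#' whose pass added them, with the stressor overlap of the full closure in
#' the subtitle.
#'
#' @param object A `closure_plan`.
#' @param effort Optional per-cell stressor vector for the legend line
#'   (defaults to the overlap recorded in the plan).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot closure_plan
#' @export
autoplot.closure_plan <- function(object, effort = NULL, ...) {
  cells <- object$cells
  overlap <- tail(object$species_stats$effort_overlap_pct, 1)
  legend_line <- if (is.na(overlap)) {
    "no effort data"
  } else {
    paste0("closure overlaps ", signif(overlap, 3), "% of total effort")
  }
  ggplot(cells, aes(.data$longitude, .data$latitude)) +
    geom_raster(aes(fill = .data$adder)) +
    scale_fill_viridis_d(na.value = "grey90", na.translate = FALSE,
                         name = "added by") +
    labs(x = "Longitude", y = "Latitude",
         title = paste0("Candidate MPA (", object$scheme, " sort)"),
         subtitle = legend_line) +
    theme_minimal()
}

#' Bar plot of relative influence
#'
#' @param fit A `delta_fit` or `brt_component`.
#' @param greyscale Use a monotone-luminance greyscale fill.
#' @return A ggplot object.
#' @export
plot_influence <- function(fit, greyscale = FALSE) {
  tab <- if (inherits(fit, "delta_fit")) {
    tidy(fit)
  } else {
    mutate(suppressWarnings(relative_influence(fit)),
           component = fit$family, .before = 1)
  }
  p <- ggplot(tab, aes(stats::reorder(.data$variable, .data$influence),
                       .data$influence)) +
    geom_col(fill = if (greyscale) "grey40" else "#2c7fb8") +
    coord_flip() +
    facet_wrap(~component) +
    labs(x = NULL, y = "relative influence (%)") +
    theme_minimal()
  p
}

#' Partial-dependence line plots
#'
#' Line plots of the marginal effect of each variable, one panel per
#' variable (the single lattice figure); pass one name for a single plot.
#'
#' @param fit A `brt_component`.
#' @param variables Variables to plot (default: all kept).
#' @param n_points Evaluation points per curve.
#' @param response_scale Exponentiate the curve (times the smearing factor
#'   given in `smear`) for display on the response scale.
#' @param smear Smearing factor used when `response_scale = TRUE`.
#' @return A ggplot object.
#' @export
plot_partial <- function(fit, variables = fit$kept_expvars, n_points = 100,
                         response_scale = FALSE, smear = 1) {
  curves <- purrr::map(variables, function(v) {
    partial_dependence(fit, v, n_points)
  }) |> list_rbind()
  if (response_scale) curves$effect <- smear * exp(curves$effect)
  ggplot(curves, aes(.data$x, .data$effect)) +
    geom_line() +
    facet_wrap(~variable, scales = "free_x") +
    labs(x = NULL,
         y = if (response_scale) "marginal effect (response scale)"
             else "marginal effect (link scale)") +
    theme_minimal()
}
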