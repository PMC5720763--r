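# Between-run variability of the whole fit→predict pipeline: the identical
# run is repeated under consecutive seeds and the per-cell coefficient of
# variation of the combined abundance surface, the spread of variable
# influence, and pointwise partial-dependence envelopes are collated.

#' Per-cell mean, standard deviation and coefficient of variation
#'
#' @param surfaces A list (>= 2) of `prediction_surface` tibbles on the
#'   identical cell set.
#' @return A tibble: `latitude`, `longitude`, `mean`, `sd` (n - 1
#'   denominator), `cv` (`sd / mean`, `NA` where the mean is 0).
#' @export
cv_surface <- function(surfaces) {
  stopifnot(length(surfaces) >= 2)
  ref <- surfaces[[1]][c("latitude", "longitude")]
  for (i in seq_along(surfaces)[-1]) {
    if (!isTRUE(all.equal(as.data.frame(ref),
                          as.data.frame(surfaces[[i]][c("latitude",
                                                        "longitude")]),
                          check.attributes = FALSE))) {
      abort(paste0("surface ", i, " is not on the same cell set"))
    }
  }
  vals <- vapply(surfaces, function(s) s$combined_index,
                 numeric(nrow(ref)))
  mu <- rowMeans(vals)
  sdev <- apply(vals, 1, sd)
  tibble(
    latitude = ref$latitude, longitude = ref$longitude,
    mean = mu, sd = sdev,
    cv = ifelse(mu == 0, NA_real_, sdev / mu)
  )
}

#' Repeat a delta BRT run and summarise between-run variability
#'
#' Runs [delta_fit()] + [predict()] `n_runs` times; run `k` uses seed
#' `base_seed + k` (or `base_seed` for every run in the degenerate
#' forced-identical mode, a self-test in which the CV surface must be exactly
#' zero). Simplification is off by default inside loops so the variable set —
#' and hence the influence and partial-dependence envelopes — stays
#' comparable across runs; with simplification on, a variable absent from a
#' run counts as influence 0 in that run.
#'
#' @param n_runs Number of repeats (>= 2).
#' @param samples,grids,resvar,expvars,config As in [delta_fit()].
#' @param base_seed Integer; run seeds are derived from it.
#' @param force_identical_seeds Use `base_seed` for every run (degenerate
#'   self-test mode).
#' @param pd_points Partial-dependence evaluation points per variable.
#' @return A `loop_summary`: `cv` (per-cell mean/sd/CV tibble), `influence`
#'   (per component x variable: min/mean/max/variance), `pd` (per component x
#'   variable x x-value: min/mean/max envelope), `n_runs`, `seeds`.
#' @export
run_loops <- function(n_runs, samples, grids, resvar,
                      expvars = attr(samples, "expvars"),
                      config = brt_config(simplify = FALSE),
                      base_seed = 1, force_identical_seeds = FALSE,
                      pd_points = 50) {
  stopifnot(n_runs >= 2)
  seeds <- if (force_identical_seeds) {
    rep(base_seed, n_runs)
  } else {
    base_seed + seq_len(n_runs)
  }
  runs <- vector("list", n_runs)
  for (k in seq_len(n_runs)) {
    cfg <- config
    cfg$seed <- as.integer(seeds[k])
    runs[[k]] <- tryCatch(
      {
        fit <- delta_fit(samples, resvar, expvars, config = cfg)
        list(fit = fit, surface = predict(fit, grids))
      },
      error = function(e) {
        abort(paste0("loop run ", k, " (seed ", seeds[k], ") failed: ",
                     conditionMessage(e)))
      }
    )
  }

  infl <- purrr::imap(runs, function(r, k) {
    comps <- purrr::compact(list(binary = r$fit$binary,
                                 gaussian = r$fit$gaussian))
    purrr::imap(comps, function(comp, nm) {
      tab <- suppressWarnings(relative_influence(comp))
      full <- tibble(component = nm, variable = expvars, run = k,
                     influence = 0)
      full$influence[match(tab$variable, expvars)] <- tab$influence
      full
    }) |> list_rbind()
  }) |> list_rbind() |>
    group_by(.data$component, .data$variable) |>
    summarise(
      min = min(.data$influence), mean = mean(.data$influence),
      max = max(.data$influence), variance = var(.data$influence),
      .groups = "drop"
    )

  pd <- purrr::imap(runs, function(r, k) {
    comps <- purrr::compact(list(binary = r$fit$binary,
                                 gaussian = r$fit$gaussian))
    purrr::imap(comps, function(comp, nm) {
      purrr::map(comp$kept_expvars, function(v) {
        mutate(partial_dependence(comp, v, n_points = pd_points),
               component = nm, run = k)
      }) |> list_rbind()
    }) |> list_rbind()
  }) |> list_rbind() |>
    group_by(.data$component, .data$variable, .data$x) |>
    summarise(
      min = min(.data$effect), mean = mean(.data$effect),
      max = max(.data$effect), .groups = "drop"
    )

  structure(
    list(
      cv = cv_surface(purrr::map(runs, "surface")),
      influence = infl, pd = pd,
      n_runs = as.integer(n_runs), seeds = seeds
    ),
    class = "loop_summary"
  )
}

#' @export
print.loop_summary <- function(x, ...) {
  cat("<loop_summary>", x$n_runs, "runs; median cell CV:",
      signif(stats::median(x$cv$cv, na.rm = TRUE), 4), "\n")
  invisible(x)
}
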