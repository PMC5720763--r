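# Run persistence: the per-run CSV and PNG artefacts of a fit, mirroring the
# suite's conventional file set so downstream tools (and people) can pick a
# run apart without R.

#' Write the standard artefact set of a fitted run
#'
#' Writes into `dir`: `abundance_preds_latlon.csv` (lat, lon, combined
#' index), `abundance_preds_full.csv` (plus explanatory values, occurrence
#' probability and positive abundance), `delta_model.rds` (reloadable model),
#' `model_report.csv`, `influence_binary.csv` / `influence_gaussian.csv`,
#' and, when `plots = TRUE`, influence bar plots, per-variable and lattice
#' partial-dependence figures and the prediction map in colour and
#' greyscale.
#'
#' @param fit A `delta_fit`.
#' @param grids Grid tibble to predict on (omit to reuse `fit$predictions`).
#' @param dir Output directory (created if needed).
#' @param plots Also render PNG figures.
#' @return The directory, invisibly.
#' @export
write_run_outputs <- function(fit, grids = NULL, dir = ".", plots = FALSE) {
  stopifnot(inherits(fit, "delta_fit"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  surface <- if (!is.null(grids)) predict(fit, grids) else fit$predictions
  if (is.null(surface)) abort("no grids given and the fit holds no predictions")

  readr::write_csv(
    select(surface, "latitude", "longitude", "combined_index"),
    file.path(dir, "abundance_preds_latlon.csv")
  )
  full <- surface
  if (!is.null(grids)) {
    full <- bind_cols(surface,
                      grids[, setdiff(fit$expvars, names(surface)),
                            drop = FALSE])
  }
  readr::write_csv(full, file.path(dir, "abundance_preds_full.csv"))
  write_delta_model(fit, file.path(dir, "delta_model.rds"))
  readr::write_csv(model_report(fit), file.path(dir, "model_report.csv"))

  comps <- purrr::compact(list(binary = fit$binary, gaussian = fit$gaussian))
  for (nm in names(comps)) {
    readr::write_csv(
      suppressWarnings(relative_influence(comps[[nm]])),
      file.path(dir, paste0("influence_", nm, ".csv"))
    )
  }

  if (plots) {
    ggsave(file.path(dir, "influence.png"), plot_influence(fit),
           width = 1920, height = 1440, units = "px", dpi = 300)
    ggsave(file.path(dir, "influence_grey.png"),
           plot_influence(fit, greyscale = TRUE),
           width = 1920, height = 1440, units = "px", dpi = 300)
    for (nm in names(comps)) {
      ggsave(file.path(dir, paste0("partial_", nm, ".png")),
             plot_partial(comps[[nm]]),
             width = 1920, height = 1440, units = "px", dpi = 300)
      for (v in comps[[nm]]$kept_expvars) {
        ggsave(file.path(dir, paste0("partial_", nm, "_", v, ".png")),
               plot_partial(comps[[nm]], variables = v),
               width = 1920, height = 1440, units = "px", dpi = 300)
      }
    }
    render_map(surface, out = file.path(dir, "abundance_map.png"))
    render_map(surface, palette = "greys",
               out = file.path(dir, "abundance_map_grey.png"))
  }
  invisible(dir)
}
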