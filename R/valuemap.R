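# Decision-support tool: greedy candidate closed areas (MPAs) that secure
# each species' escapement-biomass target (Bpa) while minimising displacement
# of a mapped stressor such as fishing effort. Cells are ranked under one of
# four sorting schemes and accumulated until the target is met; multi-species
# closures cascade, crediting each species with the biomass already inside
# earlier species' closures.

#' Specify a multi-species closure problem
#'
#' @param species Species column names in the cell table, listed in
#'   processing order (most conservationally at-risk first).
#' @param hrmsy Harvest rate at maximum sustainable yield per species, in
#'   (0, 1), same order as `species`.
#' @param scheme Sorting scheme: `"combination"` (abundance and reversed
#'   stressor averaged), `"biomass"` (abundance only), `"effort"` (stressor
#'   avoidance first), or `"conservation"` (external conservation surface).
#' @param ratios Positive importance ratios per species (default all 1).
#' @param bpa_fn Callable mapping `(hrmsy, total_biomass)` to the Bpa target;
#'   the default is escapement biomass, `(1 - hrmsy) * total_biomass`.
#' @param combine `"mean"` (default) or `"geometric"`: how the combination
#'   scheme merges scaled abundance with the reversed stressor.
#' @return A `closure_spec` list.
#' @export
closure_spec <- function(species, hrmsy, scheme = c("combination", "biomass",
                                                    "effort", "conservation"),
                         ratios = rep(1, length(species)),
                         bpa_fn = function(hrmsy, total) (1 - hrmsy) * total,
                         combine = c("mean", "geometric")) {
  scheme <- match.arg(scheme)
  combine <- match.arg(combine)
  stopifnot(length(hrmsy) == length(species), all(hrmsy > 0), all(hrmsy < 1),
            length(ratios) == length(species), all(ratios > 0),
            is.function(bpa_fn))
  structure(
    list(species = species, hrmsy = hrmsy, scheme = scheme, ratios = ratios,
         bpa_fn = bpa_fn, combine = combine),
    class = "closure_spec"
  )
}

#' Importance-scale species abundance vectors
#'
#' Multiplies each species' abundance vector by its importance ratio, then
#' divides by its own maximum so every (non-zero) species' scaled vector has
#' maximum 1. The unit-max vector itself is therefore invariant to the
#' ratio; the ratio acts as that species' weight in any cross-species sum
#' and is recorded in the `ratios` attribute.
#'
#' @param good A data frame (or named list) of per-species abundance vectors.
#' @param ratios Positive reals, one per species.
#' @return A tibble of unit-max scaled vectors with attribute `ratios`;
#'   all-zero species stay zero with a warning.
#' @export
scale_importance <- function(good, ratios = rep(1, length(good))) {
  good <- as_tibble(good)
  if (length(ratios) != ncol(good)) {
    abort(paste0("got ", length(ratios), " ratio(s) for ", ncol(good),
                 " species"))
  }
  stopifnot(all(ratios > 0))
  out <- good
  for (i in seq_along(good)) {
    v <- good[[i]] * ratios[i]
    m <- max(v, na.rm = TRUE)
    if (m == 0) {
      warn(paste0("species '", names(good)[i], "' is zero everywhere"))
      out[[i]] <- v
    } else {
      out[[i]] <- v / m
    }
  }
  attr(out, "ratios") <- stats::setNames(ratios, names(good))
  out
}

#' Combined closure metric of abundance and reversed stressor
#'
#' Scales the stressor to unit maximum, reverses it (`1 - scaled`), and
#' averages it with the unit-scaled abundance. The result runs from 0 (cell
#' to avoid closing: maximum stressor, no abundance) to 1 (cell to
#' preferentially close: no stressor, maximum abundance).
#'
#' @param good_scaled Abundance scaled to `[0, 1]` (see
#'   [scale_importance()]).
#' @param bad Stressor intensity vector, `>= 0`.
#' @param combine `"mean"` (arithmetic, default) or `"geometric"`.
#' @return A vector in `[0, 1]`.
#' @export
combined_metric <- function(good_scaled, bad, combine = c("mean",
                                                          "geometric")) {
  combine <- match.arg(combine)
  stopifnot(length(good_scaled) == length(bad))
  m <- max(bad, na.rm = TRUE)
  rev_bad <- if (m == 0) rep(1, length(bad)) else 1 - bad / m
  if (combine == "mean") {
    (good_scaled + rev_bad) / 2
  } else {
    sqrt(good_scaled * rev_bad)
  }
}

#' Rank cells for closure under a sorting scheme
#'
#' @param data A cell table with per-species abundance, a stressor column,
#'   and (for the conservation scheme) a conservation-value column.
#' @param species Name of the species column being protected.
#' @param scheme One of `"combination"`, `"biomass"`, `"effort"`,
#'   `"conservation"`.
#' @param bad Stressor column name.
#' @param conserve Conservation-value column name (conservation scheme only).
#' @param good_scaled Optional pre-scaled abundance for the combination
#'   metric (defaults to unit-max scaling of the species column).
#' @param combine Aggregator passed to [combined_metric()].
#' @return An integer permutation of the row indices, best-to-close first.
#'   All ties are broken by row index, so the ordering is deterministic.
#' @export
order_cells <- function(data, species, scheme, bad = "effort",
                        conserve = NULL, good_scaled = NULL,
                        combine = "mean") {
  n <- nrow(data)
  idx <- seq_len(n)
  abundance <- data[[species]]
  switch(scheme,
    biomass = order(-abundance, idx),
    effort = order(data[[bad]], -abundance, idx),
    combination = {
      gs <- good_scaled %||% scale_unit_max(abundance)
      order(-combined_metric(gs, data[[bad]], combine), idx)
    },
    conservation = {
      if (is.null(conserve) || !conserve %in% names(data)) {
        abort("conservation sort needs a conservation-value column")
      }
      order(-data[[conserve]], idx)
    },
    abort(paste0("unknown sorting scheme: ", scheme))
  )
}

#' Accumulate ranked cells until a biomass target is met
#'
#' Walks the ordering, accumulating the species' abundance, and stops at the
#' first cell where the cumulative sum reaches `bpa_target`; the returned
#' member set is that prefix (greedy-minimal for the given ordering).
#'
#' @param ordering Integer cell ordering (from [order_cells()]).
#' @param abundance Per-cell abundance of the species being protected.
#' @param bpa_target Required protected biomass, `>= 0`.
#' @return Integer vector of member cell indices (possibly empty).
#' @export
build_closure <- function(ordering, abundance, bpa_target) {
  if (bpa_target <= 0) return(integer(0))
  tol <- 1e-9 * max(1, abs(bpa_target))
  total <- sum(abundance[ordering])
  if (total < bpa_target - tol) {
    abort(paste0("target ", format(bpa_target), " unattainable: at most ",
                 format(total), " available"))
  }
  cum <- cumsum(abundance[ordering])
  stop_at <- which(cum >= bpa_target - tol)[1]
  ordering[seq_len(stop_at)]
}

#' Cascading multi-species closure plan
#'
#' Processes species in at-risk order. The first species' closure is built
#' from scratch; each later species is first credited with its own abundance
#' inside the union of all earlier closures, then adds cells from its own
#' ordering (skipping existing members) until its Bpa target is met. Each
#' cell is attributed to the species whose pass added it, yielding the
#' multi-colour MPA map; the stressor overlap of the growing closure is
#' recorded after every pass.
#'
#' @param data Cell table: `latitude`, `longitude`, one abundance column per
#'   species, the stressor column, optionally a conservation column.
#' @param spec A [closure_spec()].
#' @param bad Stressor column name (default `"effort"`).
#' @param conserve Conservation-value column name.
#' @return A `closure_plan`: `cells` (tibble with `member` flag and `adder`
#'   attribution), `species_stats` (per species: Bpa target, biomass credited
#'   and protected at pass time, final protected biomass, cells added,
#'   cumulative stressor overlap %), `scheme`.
#' @export
cascade_closures <- function(data, spec, bad = "effort", conserve = NULL) {
  stopifnot(inherits(spec, "closure_spec"))
  data <- as_tibble(data)
  missing_sp <- setdiff(spec$species, names(data))
  if (length(missing_sp) > 0) {
    abort(paste0("species column(s) not found: ",
                 paste(missing_sp, collapse = ", ")))
  }
  for (cn in c(spec$species, bad)) {
    if (any(data[[cn]] < 0, na.rm = TRUE)) {
      abort(paste0("negative values in column '", cn, "'"))
    }
  }
  n <- nrow(data)
  scaled <- scale_importance(data[spec$species], spec$ratios)
  member <- logical(n)
  adder <- rep(NA_character_, n)
  stats_rows <- list()

  for (k in seq_along(spec$species)) {
    sp <- spec$species[k]
    abundance <- data[[sp]]
    target <- spec$bpa_fn(spec$hrmsy[k], sum(abundance))
    credited <- sum(abundance[member])
    added <- integer(0)
    last_added <- NA_integer_
    if (credited < target) {
      ordering <- order_cells(data, sp, spec$scheme, bad = bad,
                              conserve = conserve,
                              good_scaled = scaled[[sp]],
                              combine = spec$combine)
      ordering <- ordering[!member[ordering]]
      added <- build_closure(ordering, abundance, target - credited)
      if (length(added) > 0) last_added <- added[length(added)]
      member[added] <- TRUE
      adder[added] <- sp
    }
    stats_rows[[k]] <- tibble(
      species = sp, hrmsy = spec$hrmsy[k],
      total_biomass = sum(abundance), bpa_target = target,
      credited_biomass = credited,
      protected_at_pass = credited + sum(abundance[added]),
      cells_added = length(added), last_added_cell = last_added,
      effort_overlap_pct = effort_overlap(which(member), data[[bad]])
    )
  }

  plan <- structure(
    list(
      cells = tibble(
        cell = seq_len(n), latitude = data$latitude,
        longitude = data$longitude, member = member, adder = adder
      ),
      species_stats = mutate(
        list_rbind(stats_rows),
        protected_final = map_dbl(spec$species,
                                  function(sp) sum(data[[sp]][member]))
      ),
      scheme = spec$scheme, spec = spec, bad = bad
    ),
    class = "closure_plan"
  )
  plan
}

#' @export
print.closure_plan <- function(x, ...) {
  cat("<closure_plan> scheme:", x$scheme, " cells closed:",
      sum(x$cells$member), "/", nrow(x$cells), "\n")
  print(x$species_stats)
  invisible(x)
}

#' Stressor overlap of a closure
#'
#' The percentage of the stressor's study-area total that falls inside the
#' member cells — the headline displacement number quoted in map legends.
#'
#' @param members Integer indices (or logical mask) of member cells.
#' @param bad Per-cell stressor intensity.
#' @return A percentage in `[0, 100]`; `NA` with attribute
#'   `legend = "no effort data"` when the stressor total is zero.
#' @export
effort_overlap <- function(members, bad) {
  total <- sum(bad, na.rm = TRUE)
  if (total == 0) {
    out <- NA_real_
    attr(out, "legend") <- "no effort data"
    return(out)
  }
  100 * sum(bad[members], na.rm = TRUE) / total
}
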