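# Conservation surface amalgamation: predicted-abundance surfaces of several
# species (or life-history subsets) are each scaled to unit maximum before
# being summed, so an abundant subset cannot swamp a rare — often more
# threatened — one. Weights then express conservation priority explicitly.

#' Scale a surface to unit maximum
#'
#' @param x A numeric vector, or a `prediction_surface` (its
#'   `combined_index` is used).
#' @return Values divided by their maximum (an all-zero input returns zeros
#'   with a warning). `NA` cells stay `NA`.
#' @export
scale_unit_max <- function(x) {
  v <- if (inherits(x, "prediction_surface")) x$combined_index else x
  if (length(v) == 0) abort("empty surface")
  m <- max(v, na.rm = TRUE)
  if (!is.finite(m) || m == 0) {
    warn("surface is zero everywhere: returning zeros")
    return(v)
  }
  v / m
}

#' Combine species surfaces into a conservation-priority surface
#'
#' Each subset surface is scaled (unit maximum by default, unit sum as an
#' alternative) and the weighted sum taken per cell. All surfaces must cover
#' the identical cell set.
#'
#' @param surfaces A named list of `prediction_surface` tibbles (or tibbles
#'   with `latitude`, `longitude`, `combined_index`).
#' @param weights Positive weights, one per surface (default all 1).
#' @param scale `"max"` (unit maximum, the default) or `"sum"` (unit sum).
#' @return A `conservation_surface` tibble: `latitude`, `longitude`, one
#'   scaled column per subset, and `total`.
#' @export
combine_subsets <- function(surfaces, weights = rep(1, length(surfaces)),
                            scale = c("max", "sum")) {
  scale <- match.arg(scale)
  stopifnot(length(surfaces) >= 1, length(weights) == length(surfaces),
            all(weights > 0))
  if (is.null(names(surfaces))) {
    names(surfaces) <- paste0("subset_", seq_along(surfaces))
  }
  ref <- surfaces[[1]][c("latitude", "longitude")]
  for (i in seq_along(surfaces)[-1]) {
    cur <- surfaces[[i]][c("latitude", "longitude")]
    if (nrow(cur) != nrow(ref) ||
        !isTRUE(all.equal(as.data.frame(ref), as.data.frame(cur),
                          check.attributes = FALSE))) {
      extra <- anti_join(cur, ref, by = c("latitude", "longitude"))
      missing <- anti_join(ref, cur, by = c("latitude", "longitude"))
      abort(paste0(
        "surface '", names(surfaces)[i], "' is not on the same cell set; ",
        nrow(extra), " extra and ", nrow(missing), " missing cell(s)",
        if (nrow(extra) > 0) paste0(
          "; first extra: lon=", extra$longitude[1], " lat=",
          extra$latitude[1]
        )
      ))
    }
  }
  out <- as_tibble(ref)
  total <- rep(0, nrow(ref))
  for (i in seq_along(surfaces)) {
    v <- surfaces[[i]]$combined_index
    s <- if (scale == "max") {
      scale_unit_max(v)
    } else if (sum(v, na.rm = TRUE) == 0) {
      warn("surface is zero everywhere: returning zeros")
      v
    } else {
      v / sum(v, na.rm = TRUE)
    }
    out[[names(surfaces)[i]]] <- s
    total <- total + weights[i] * s
  }
  out$total <- total
  attr(out, "weights") <- stats::setNames(weights, names(surfaces))
  class(out) <- c("conservation_surface", class(out))
  out
}
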