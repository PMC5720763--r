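#' Read a survey samples table from CSV
#'
#' Reads survey stations (one row per haul/station) holding coordinates,
#' explanatory variables and at least one non-negative response variable such
#' as CPUE. Rows with a missing response are dropped with a message; negative
#' responses are an error because a catch rate cannot be negative.
#'
#' @param path Path to a CSV file (comma separated, header row, `.` decimal).
#' @param resvars Character vector of response variable column names.
#' @param expvars Character vector of explanatory variable column names.
#' @param lat,lon Names of the latitude / longitude columns (decimal degrees,
#'   WGS84).
#' @return A tibble with standardised `latitude` and `longitude` columns, the
#'   requested explanatory and response columns, and attributes `expvars` and
#'   `resvars` recording the roles.
#' @export
read_samples <- function(path, resvars, expvars,
                         lat = "latitude", lon = "longitude") {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_samples(raw, resvars = resvars, expvars = expvars, lat = lat, lon = lon)
}

#' Validate an in-memory data frame as a samples table
#'
#' @param data A data frame of survey stations.
#' @inheritParams read_samples
#' @return A validated samples tibble (see [read_samples()]).
#' @export
as_samples <- function(data, resvars, expvars,
                       lat = "latitude", lon = "longitude") {
  need <- c(lat, lon, expvars, resvars)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("samples table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(expvars)) abort("explanatory variable names must be unique")
  out <- as_tibble(data)
  out <- rename(out, latitude = all_of(lat), longitude = all_of(lon))
  out <- select(out, "latitude", "longitude", all_of(expvars), all_of(resvars))
  if (nrow(out) == 0) abort("samples table has no rows")
  if (anyNA(out$latitude) || anyNA(out$longitude)) {
    abort("missing latitude/longitude in samples table")
  }
  # stations where the response was not recorded carry no information for the
  # hurdle model; drop rather than impute
  miss <- rowSums(is.na(out[resvars])) > 0
  if (any(miss)) {
    inform(paste0("dropped ", sum(miss), " row(s) with missing response"))
    out <- out[!miss, , drop = FALSE]
    if (nrow(out) == 0) abort("all rows had missing response values")
  }
  for (rv in resvars) {
    bad <- which(out[[rv]] < 0)
    if (length(bad) > 0) {
      abort(paste0("response '", rv, "' is negative in row(s): ",
                   paste(head(bad, 10), collapse = ", ")))
    }
  }
  attr(out, "expvars") <- expvars
  attr(out, "resvars") <- resvars
  out
}

#' Read a prediction grid table from CSV
#'
#' The grid holds cell centroids of a (nominally regular) lattice plus the
#' same explanatory variables as the samples table; the response is unknown
#' here and will be predicted.
#'
#' @inheritParams read_samples
#' @return A tibble with `latitude`, `longitude` and explanatory columns,
#'   attribute `expvars`.
#' @export
read_grids <- function(path, expvars, lat = "latitude", lon = "longitude") {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_grids(raw, expvars = expvars, lat = lat, lon = lon)
}

#' Validate an in-memory data frame as a grid table
#' @param data A data frame of grid cell centroids.
#' @inheritParams read_grids
#' @return A validated grid tibble.
#' @export
as_grids <- function(data, expvars, lat = "latitude", lon = "longitude") {
  need <- c(lat, lon, expvars)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("grids table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  out <- as_tibble(data)
  out <- rename(out, latitude = all_of(lat), longitude = all_of(lon))
  out <- select(out, "latitude", "longitude", all_of(expvars))
  if (nrow(out) == 0) abort("grids table has no rows")
  if (anyNA(out$latitude) || anyNA(out$longitude)) {
    abort("missing latitude/longitude in grids table")
  }
  if (anyDuplicated(out[c("latitude", "longitude")]) > 0) {
    abort("duplicate cell centroids in grids table")
  }
  attr(out, "expvars") <- expvars
  out
}

#' Check that samples and grids carry matching explanatory variables
#'
#' Confirms every requested explanatory variable exists in both tables and
#' reports, per variable, the sampled and gridded ranges. Grid ranges that
#' extend beyond the sampled range are flagged as extrapolation (a warning,
#' not an error): predictions there are unsupported by data.
#'
#' @param samples A samples tibble.
#' @param grids A grid tibble.
#' @param expvars Explanatory variable names to check (default: the samples
#'   table's recorded set).
#' @return A tibble with one row per variable: sampled and grid min/max and an
#'   `extrapolated` flag.
#' @export
validate_match <- function(samples, grids,
                           expvars = attr(samples, "expvars")) {
  miss_s <- setdiff(expvars, names(samples))
  miss_g <- setdiff(expvars, names(grids))
  if (length(miss_s) + length(miss_g) > 0) {
    abort(paste0(
      "explanatory variable name mismatch",
      if (length(miss_s)) paste0("; absent from samples: ",
                                 paste(miss_s, collapse = ", ")),
      if (length(miss_g)) paste0("; absent from grids: ",
                                 paste(miss_g, collapse = ", "))
    ))
  }
  report <- purrr::map(expvars, function(v) {
    tibble(
      variable = v,
      sample_min = min(samples[[v]], na.rm = TRUE),
      sample_max = max(samples[[v]], na.rm = TRUE),
      grid_min = min(grids[[v]], na.rm = TRUE),
      grid_max = max(grids[[v]], na.rm = TRUE)
    )
  }) |> list_rbind()
  report$extrapolated <- report$grid_min < report$sample_min |
    report$grid_max > report$sample_max
  if (any(report$extrapolated)) {
    warn(paste0("grid range extends beyond sampled range for: ",
                paste(report$variable[report$extrapolated], collapse = ", ")))
  }
  report
}

#' Test a response vector for zero inflation
#'
#' The delta (hurdle) pathway is warranted when exact zeros make up a large
#' share of the observations. The rule used here is proportion-based: the
#' vector is called zero inflated when the fraction of exact zeros is at
#' least `threshold`.
#'
#' @param values Non-negative response values.
#' @param threshold Minimum proportion of exact zeros (default 0.5).
#' @return `TRUE` or `FALSE`.
#' @export
check_zero_inflation <- function(values, threshold = 0.5) {
  if (length(values) == 0) abort("empty response vector")
  if (any(values < 0, na.rm = TRUE)) abort("response values must be >= 0")
  mean(values == 0, na.rm = TRUE) >= threshold
}

#' Split a samples table into hurdle components
#'
#' Builds the two response sets of the delta log-normal model: a presence /
#' absence indicator over all stations, and the positive-catch subset with the
#' response replaced by its natural logarithm.
#'
#' @param samples A samples tibble.
#' @param resvar Name of the response variable to split.
#' @return A list with `binary` (0/1 integer vector, length `nrow(samples)`)
#'   and `positive` (tibble of the rows with `resvar > 0`, response replaced
#'   by `log(resvar)`).
#' @export
split_binary_gaussian <- function(samples, resvar) {
  if (!resvar %in% names(samples)) {
    abort(paste0("response '", resvar, "' not found"))
  }
  y <- samples[[resvar]]
  binary <- as.integer(y > 0)
  if (all(binary == 0L)) {
    abort("response is zero everywhere: no positive-catch component exists")
  }
  positive <- samples[binary == 1L, , drop = FALSE]
  positive[[resvar]] <- log(positive[[resvar]])
  list(binary = binary, positive = as_tibble(positive))
}

#' Minimum feasible bag fractions for a delta BRT run
#'
#' Boosting subsamples `bf` of the training rows at every iteration; with few
#' rows and a small `bf` the per-iteration subsample can fall below what a
#' tree fitter will accept, failing the run. This reports, for the occurrence
#' component (all rows) and the positive-catch component (rows with
#' `resvar > 0`), the smallest bag fraction on a 0.01 grid whose subsample
#' still holds at least `min_train_rows` rows, i.e. the smallest `bf` with
#' `floor(bf * n) >= min_train_rows`.
#'
#' @param samples A samples tibble.
#' @param resvar Response variable name.
#' @param min_train_rows Smallest acceptable per-iteration training subsample
#'   (default 21).
#' @return A tibble with one row per component: `component`, `n`, `bf_min`
#'   (NA when infeasible) and `feasible`.
#' @export
bfcheck <- function(samples, resvar, min_train_rows = 21) {
  if (!resvar %in% names(samples)) {
    abort(paste0("response '", resvar, "' not found"))
  }
  stopifnot(min_train_rows >= 1)
  y <- samples[[resvar]]
  n_bin <- length(y)
  n_gaus <- sum(y > 0)
  purrr::map2(
    c("binary", "gaussian"), c(n_bin, n_gaus),
    function(comp, n) {
      bf <- bf_minimum(n, min_train_rows)
      tibble(component = comp, n = n, bf_min = bf, feasible = !is.na(bf))
    }
  ) |> list_rbind()
}

# Smallest bf in {0.01, ..., 1.00} with floor(bf * n) >= m, computed in
# integer arithmetic ((k * n) %/% 100 with bf = k/100) so no floating-point
# rounding can shift the boundary. NA when even bf = 1 fails.
bf_minimum <- function(n, m) {
  if (n < m) return(NA_real_)
  for (k in 1:100) {
    if ((k * n) %/% 100 >= m) return(k / 100)
  }
  NA_real_
}
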