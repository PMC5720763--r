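# Representativeness Surface Builder: how well does the survey cover the
# explanatory-variable space at each prediction cell? Per variable, sample
# and grid values are binned over the grid's range (the prediction universe);
# a cell's score is the absolute difference between the sample and grid
# relative frequency of the cell's own bin. High scores flag cells whose
# environmental neighbourhood the survey under- or over-represents, where
# predicted-abundance maps deserve caution.

#' Binned relative frequencies of a variable in samples and grids
#'
#' Bins both vectors into `n_bins` equal-width intervals spanning the *grids*
#' range. Sample values outside that range are clamped into the end bins.
#'
#' @param values_samples,values_grids Numeric vectors (non-empty).
#' @param n_bins Number of bins (>= 2, default 10).
#' @return A list: `edges` (length `n_bins + 1`), `samples_freq`,
#'   `grids_freq` (each summing to 1), or `NULL` (with a warning) when the
#'   grids variable is constant and no bins can be formed.
#' @export
bin_frequencies <- function(values_samples, values_grids, n_bins = 10) {
  stopifnot(length(values_samples) > 0, length(values_grids) > 0,
            n_bins >= 2)
  r <- range(values_grids, na.rm = TRUE)
  if (r[1] == r[2]) {
    warn("constant grids variable: skipped (single degenerate bin)")
    return(NULL)
  }
  edges <- seq(r[1], r[2], length.out = n_bins + 1)
  freq <- function(v) {
    b <- bin_index(v, edges)
    tabulate(b, nbins = n_bins) / sum(!is.na(b))
  }
  list(edges = edges, samples_freq = freq(values_samples),
       grids_freq = freq(values_grids))
}

# Bin membership with clamping to the end bins; right-closed except the first
# bin, which includes its lower edge.
bin_index <- function(v, edges) {
  n_bins <- length(edges) - 1
  b <- findInterval(v, edges, rightmost.closed = TRUE, left.open = TRUE)
  b[!is.na(b) & b < 1] <- 1L
  b[!is.na(b) & b > n_bins] <- n_bins
  b
}

#' Representativeness scores for every grid cell
#'
#' For each explanatory variable and each grid cell: the absolute difference
#' between the samples' and the grids' relative frequency of the bin holding
#' the cell's value, summed over variables into a total. Higher totals mean
#' poorer survey coverage of that cell's environmental conditions. An exact
#' stratified replica of the grid's bin proportions scores 0 everywhere.
#'
#' @param samples A samples tibble.
#' @param grids A grid tibble.
#' @param expvars Explanatory variables to score (default: the samples
#'   table's recorded set).
#' @param n_bins Bins per variable (default 10); the main tuning knob.
#' @param signed If `TRUE`, per-variable scores keep their sign
#'   (positive = bin under-sampled relative to the grid); the total remains
#'   the sum of absolute values.
#' @return An `rsb_surface` tibble: `latitude`, `longitude`, one score column
#'   per variable (`rsb_<var>`), and `total`.
#' @export
rsb_scores <- function(samples, grids, expvars = attr(samples, "expvars"),
                       n_bins = 10, signed = FALSE) {
  validate_match(samples, grids, expvars)
  out <- tibble(latitude = grids$latitude, longitude = grids$longitude)
  total <- rep(0, nrow(grids))
  for (v in expvars) {
    bf <- bin_frequencies(samples[[v]], grids[[v]], n_bins)
    if (is.null(bf)) next
    cell_bin <- bin_index(grids[[v]], bf$edges)
    diff <- bf$samples_freq[cell_bin] - bf$grids_freq[cell_bin]
    out[[paste0("rsb_", v)]] <- if (signed) -diff else abs(diff)
    total <- total + abs(diff)
  }
  out$total <- total
  class(out) <- c("rsb_surface", class(out))
  out
}

#' Representativeness surfaces for a fitted delta model
#'
#' Scores coverage for the variable set kept by the occurrence component, by
#' the positive-abundance component, and by their union — the three surfaces
#' relevant to interpreting the combined prediction map.
#'
#' @param samples,grids As in [rsb_scores()].
#' @param model A `delta_fit`.
#' @param n_bins Bins per variable.
#' @return A named list of `rsb_surface` tibbles: `binary`, `gaussian`,
#'   `combined`.
#' @export
rsb_for_model <- function(samples, grids, model, n_bins = 10) {
  stopifnot(inherits(model, "delta_fit"))
  vb <- if (!is.null(model$binary)) model$binary$kept_expvars else character(0)
  vg <- if (!is.null(model$gaussian)) model$gaussian$kept_expvars else
    character(0)
  score <- function(v) {
    if (length(v) == 0) return(NULL)
    rsb_scores(samples, grids, expvars = v, n_bins = n_bins)
  }
  purrr::compact(list(binary = score(vb), gaussian = score(vg),
                      combined = score(union(vb, vg))))
}
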