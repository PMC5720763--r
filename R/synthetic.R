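# Synthetic study systems with known truth: a smooth multivariate
# environmental landscape on a regular lattice, a hurdle (delta log-normal)
# survey process over it, and a fishing-effort surface with a controllable
# rank correlation to true abundance. Everything is deterministic given a
# seed, and the closed-form expected abundance per cell is exported so
# recovery can be measured exactly.

#' Default generative truth for the synthetic system
#'
#' Four standardized environmental fields, two of which drive both the
#' occurrence and the positive-abundance process (the other two are pure
#' noise). The occurrence intercept is set so roughly half to 60% of survey
#' catches are exact zeros — the hallmark of trawl-survey CPUE — and the
#' log-scale noise gives the long right tail.
#'
#' @param occ_intercept,occ_coef Logistic-link occurrence model.
#' @param abn_intercept,abn_coef Log-link positive-abundance model.
#' @param log_sd Log-scale noise standard deviation.
#' @return A `truth_model` list of the generative constants.
#' @export
truth_model <- function(occ_intercept = -0.5, occ_coef = c(1, 1, 0, 0),
                        abn_intercept = 1, abn_coef = c(0.8, 0.5, 0, 0),
                        log_sd = 0.7) {
  stopifnot(length(occ_coef) == length(abn_coef), log_sd >= 0)
  structure(
    list(
      occ_intercept = occ_intercept, occ_coef = occ_coef,
      abn_intercept = abn_intercept, abn_coef = abn_coef,
      log_sd = log_sd,
      expvars = paste0("x", seq_along(occ_coef))
    ),
    class = "truth_model"
  )
}

# Separable Gaussian smoothing of a lattice field (reflection padding).
smooth_field <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  w <- exp(-((-half):half)^2 / (2 * sigma^2))
  w <- w / sum(w)
  pad_filter <- function(v) {
    padded <- c(rev(v[seq_len(half)]), v,
                rev(v[(length(v) - half + 1):length(v)]))
    stats::filter(padded, w, sides = 2)[(half + 1):(half + length(v))]
  }
  m <- apply(m, 2, pad_filter)
  t(apply(m, 1, pad_filter))
}

#' Generate a smooth environmental landscape on a regular lattice
#'
#' Each explanatory variable is a low-order linear spatial trend plus
#' Gaussian-smoothed white noise, standardized to mean 0 and unit standard
#' deviation over the lattice. Trend directions are drawn from the seed.
#'
#' @param n_lon,n_lat Lattice size (>= 2 each); cells are 0.05 degrees.
#' @param truth A [truth_model()] fixing how many variables to build.
#' @param seed Integer seed.
#' @param noise_sd Standard deviation of the white-noise field before
#'   smoothing (0 gives purely linear fields).
#' @param smooth_sigma Gaussian smoothing radius in cells.
#' @param trend_sd Scale of the random linear trend coefficients.
#' @return A list: `grid` (tibble with `latitude`, `longitude`, the
#'   standardized fields, attribute `expvars`) and `truth` (the input truth
#'   with per-cell `eta_occ`, `eta_abn`, `p_occ` and closed-form
#'   `true_abundance = plogis(eta_occ) * exp(eta_abn + log_sd^2 / 2)`
#'   attached).
#' @export
gen_landscape <- function(n_lon = 40, n_lat = 40, truth = truth_model(),
                          seed = 1, noise_sd = 1, smooth_sigma = 2,
                          trend_sd = 0.3) {
  stopifnot(n_lon >= 2, n_lat >= 2)
  p <- length(truth$expvars)
  lon <- seq(-6, by = 0.05, length.out = n_lon)
  lat <- seq(53, by = 0.05, length.out = n_lat)
  grid <- tidyr::expand_grid(latitude = lat, longitude = lon)
  # normalized lattice coordinates for the trends
  u <- (grid$longitude - min(lon)) / (max(lon) - min(lon)) - 0.5
  v <- (grid$latitude - min(lat)) / (max(lat) - min(lat)) - 0.5
  fields <- with_seed(seed, {
    lapply(seq_len(p), function(j) {
      a <- rnorm(2, sd = trend_sd)
      f <- a[1] * u + a[2] * v
      if (noise_sd > 0) {
        noise <- matrix(rnorm(n_lat * n_lon, sd = noise_sd), n_lat, n_lon)
        f <- f + as.vector(t(smooth_field(noise, smooth_sigma)))
      }
      (f - mean(f)) / sd(f)
    })
  })
  for (j in seq_len(p)) grid[[truth$expvars[j]]] <- fields[[j]]
  attr(grid, "expvars") <- truth$expvars

  X <- as.matrix(grid[, truth$expvars])
  truth$eta_occ <- truth$occ_intercept + as.vector(X %*% truth$occ_coef)
  truth$eta_abn <- truth$abn_intercept + as.vector(X %*% truth$abn_coef)
  truth$p_occ <- plogis(truth$eta_occ)
  truth$true_abundance <- truth$p_occ *
    exp(truth$eta_abn + truth$log_sd^2 / 2)
  list(grid = grid, truth = truth)
}

#' Simulate a hurdle survey over a landscape
#'
#' Stations are drawn without replacement from the grid cells (uniformly, or
#' preferentially towards high values of `bias_var` — the biased design
#' exists to make representativeness scores non-trivially positive). The
#' catch at a station is `Bernoulli(plogis(eta_occ)) * LogNormal(eta_abn,
#' log_sd)`, named `cpue`.
#'
#' @param grid A landscape grid from [gen_landscape()].
#' @param truth The matching `truth_model` (with per-cell linear predictors).
#' @param n_stations Number of stations (<= number of cells).
#' @param seed Integer seed.
#' @param bias_var Optional explanatory variable name towards whose high
#'   values station placement is biased.
#' @param bias_strength Log-linear weight of the bias (default 2).
#' @return A samples tibble with response `cpue`, plus a `cell` column
#'   recording each station's grid row.
#' @export
gen_survey <- function(grid, truth, n_stations = 1000, seed = 1,
                       bias_var = NULL, bias_strength = 2) {
  n_cells <- nrow(grid)
  stopifnot(n_stations <= n_cells)
  with_seed(seed + 1L, {
    w <- if (is.null(bias_var)) {
      NULL
    } else {
      exp(bias_strength * grid[[bias_var]])
    }
    cells <- sample(n_cells, n_stations, replace = FALSE, prob = w)
    occ <- rbinom(n_stations, 1, truth$p_occ[cells])
    pos <- exp(rnorm(n_stations, truth$eta_abn[cells], truth$log_sd))
    out <- grid[cells, , drop = FALSE]
    out$cpue <- occ * pos
    out$cell <- cells
    out <- as_tibble(out)
    attr(out, "expvars") <- truth$expvars
    attr(out, "resvars") <- "cpue"
    out
  })
}

#' Simulate a fishing-effort surface with controlled rank correlation
#'
#' Builds a log-normal effort field whose Spearman correlation with the true
#' expected abundance approximates `correlation`, by mixing the abundance
#' field's normal scores with independent noise (the mixing weight uses the
#' normal-score relation `rho_pearson = 2 * sin(pi * rho_spearman / 6)`).
#'
#' @param grid A landscape grid.
#' @param truth The matching `truth_model`.
#' @param correlation Target Spearman correlation in `[-1, 1]`.
#' @param seed Integer seed.
#' @return Non-negative effort values, one per grid cell.
#' @export
gen_effort <- function(grid, truth, correlation = 0, seed = 1) {
  stopifnot(correlation >= -1, correlation <= 1)
  n <- nrow(grid)
  base <- qnorm(rank(truth$true_abundance, ties.method = "average") /
                  (n + 1))
  rho <- 2 * sin(pi * correlation / 6)
  with_seed(seed + 2L, {
    z <- rho * base + sqrt(1 - rho^2) * rnorm(n)
    exp(z)
  })
}
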