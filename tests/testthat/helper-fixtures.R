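# Shared fixtures, built in code and cached per test run.

`%||%` <- function(x, y) if (is.null(x)) y else x

fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (!exists(key, envir = fixture_cache)) {
    assign(key, build(), envir = fixture_cache)
  }
  get(key, envir = fixture_cache)
}

# Small landscape + survey used by most model tests.
tiny_system <- function() {
  cached("tiny_system", function() {
    land <- gen_landscape(20, 20, seed = 42)
    samples <- gen_survey(land$grid, land$truth, n_stations = 300, seed = 42)
    list(land = land, samples = samples)
  })
}

# A quick delta fit on the tiny system (no simplification, 3 folds).
tiny_fit <- function() {
  cached("tiny_fit", function() {
    sys <- tiny_system()
    suppressWarnings(delta_fit(
      sys$samples, "cpue",
      config = brt_config(tc = 2, lr = 0.05, bf = 0.6, cv_folds = 3,
                          seed = 42, simplify = FALSE)
    ))
  })
}

# Single-component fit on data with one informative and one noise variable.
signal_noise_component <- function(seed = 1, n = 1000, family = "gaussian") {
  set.seed(seed)
  X <- cbind(x1 = runif(n, -2, 2), x2 = runif(n, -2, 2))
  y <- if (family == "bernoulli") {
    rbinom(n, 1, plogis(2 * X[, "x1"]))
  } else {
    sin(X[, "x1"]) + rnorm(n, 0, 0.3)
  }
  suppressWarnings(
    fit_component(X, y, family, tc = 2, lr = 0.1, bf = 0.7,
                  cv_folds = 3, seed = seed)
  )
}

# Random toy decision-support instance: a small cell table with 2-4 species,
# lognormal abundance fields and an independent lognormal effort field.
toy_dst_instance <- function(seed, n_cells = NULL, n_species = NULL) {
  set.seed(seed)
  n_cells <- n_cells %||% sample(20:200, 1)
  n_species <- n_species %||% sample(2:4, 1)
  data <- tibble::tibble(
    latitude = 50 + seq_len(n_cells) * 0.01,
    longitude = rep(-5, n_cells)
  )
  species <- paste0("sp", seq_len(n_species))
  for (s in species) data[[s]] <- exp(rnorm(n_cells, 0, 1))
  data$effort <- exp(rnorm(n_cells, 0, 1))
  data$conserve <- exp(rnorm(n_cells, 0, 1))
  spec <- closure_spec(
    species = species,
    hrmsy = runif(n_species, 0.05, 0.3),
    scheme = "combination"
  )
  list(data = data, spec = spec)
}

# Independent brute-force cascade oracle: naive loops, no shared code with
# cascade_closures() beyond the input format. Bpa = (1 - hrmsy) * total.
brute_force_cascade <- function(data, species, hrmsy, scheme = "biomass",
                                bad = "effort") {
  n <- nrow(data)
  member <- rep(FALSE, n)
  adder <- rep(NA_character_, n)
  for (k in seq_along(species)) {
    ab <- data[[species[k]]]
    target <- (1 - hrmsy[k]) * sum(ab)
    got <- sum(ab[member])
    # rank remaining cells by repeatedly scanning for the best one
    score <- switch(scheme,
      biomass = ab,
      effort = -data[[bad]] + 1e-12 * ab,
      stop("oracle supports biomass/effort")
    )
    remaining <- which(!member)
    while (got < target - 1e-9 * max(1, target) && length(remaining) > 0) {
      best <- remaining[1]
      for (i in remaining) {
        if (score[i] > score[best] + 1e-15) best <- i
        # ties fall through to the lower index, matching the tool
      }
      member[best] <- TRUE
      adder[best] <- species[k]
      got <- got + ab[best]
      remaining <- remaining[remaining != best]
    }
  }
  list(member = member, adder = adder)
}
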