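test_that("read_samples parses, validates and reports problems by name", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("lat,lon,depth,cpue",
               "53.1,-5.2,40,0",
               "53.2,-5.3,55,2.5",
               "53.3,-5.4,70,1.1"), path)
  s <- read_samples(path, resvars = "cpue", expvars = "depth",
                    lat = "lat", lon = "lon")
  expect_equal(nrow(s), 3)
  expect_named(s, c("latitude", "longitude", "depth", "cpue"))
  expect_equal(attr(s, "expvars"), "depth")
  expect_equal(attr(s, "resvars"), "cpue")

  expect_error(
    read_samples(path, resvars = "cpue", expvars = "salinity",
                 lat = "lat", lon = "lon"),
    "salinity"
  )

  writeLines(c("lat,lon,depth,cpue",
               "53.1,-5.2,40,0",
               "53.2,-5.3,55,-1"), path)
  expect_error(
    read_samples(path, resvars = "cpue", expvars = "depth",
                 lat = "lat", lon = "lon"),
    "row\\(s\\): 2"
  )
})

test_that("rows with missing response are dropped with a message", {
  df <- data.frame(latitude = c(1, 2, 3), longitude = c(1, 2, 3),
                   depth = c(10, 20, 30), cpue = c(1, NA, 2))
  expect_message(
    s <- as_samples(df, resvars = "cpue", expvars = "depth"),
    "dropped 1 row"
  )
  expect_equal(nrow(s), 2)
})

test_that("validate_match flags name mismatches and extrapolation", {
  samples <- as_samples(
    data.frame(latitude = 1:3, longitude = 1:3,
               depth = c(10, 50, 100), salinity = c(30, 32, 34),
               cpue = c(0, 1, 2)),
    resvars = "cpue", expvars = c("depth", "salinity")
  )
  grids_ok <- as_grids(
    data.frame(latitude = 1:4, longitude = 2:5,
               depth = c(20, 40, 60, 90), salinity = c(31, 32, 33, 33.5)),
    expvars = c("depth", "salinity")
  )
  rep <- validate_match(samples, grids_ok)
  expect_false(any(rep$extrapolated))

  grids_wide <- as_grids(
    data.frame(latitude = 1:2, longitude = 1:2,
               depth = c(0, 200), salinity = c(31, 33)),
    expvars = c("depth", "salinity")
  )
  expect_warning(rep2 <- validate_match(samples, grids_wide), "depth")
  expect_true(rep2$extrapolated[rep2$variable == "depth"])
  expect_false(rep2$extrapolated[rep2$variable == "salinity"])

  expect_error(
    validate_match(samples, grids_ok, expvars = c("depth", "temperature")),
    "temperature"
  )
})

test_that("zero-inflation rule is proportion-based, boundary-inclusive and
           monotone in the threshold", {
  expect_true(check_zero_inflation(c(0, 0, 0, 1, 2), 0.5))
  expect_false(check_zero_inflation(c(1, 2, 3), 0.01))
  expect_true(check_zero_inflation(c(0, 1), 0.5))
  expect_error(check_zero_inflation(numeric(0)), "empty")

  # monotonicity: true at t implies true at every t' <= t
  set.seed(7)
  for (i in 1:20) {
    v <- rbinom(50, 1, 0.5) * rexp(50)
    ts <- seq(0.05, 1, by = 0.05)
    res <- vapply(ts, function(t) check_zero_inflation(v, t), logical(1))
    expect_true(all(diff(as.integer(res)) <= 0))
  }
})

test_that("hurdle split is exact and reversible", {
  s <- as_samples(
    data.frame(latitude = 1:4, longitude = 1:4, depth = 1:4,
               cpue = c(0, 2, 0, exp(1))),
    resvars = "cpue", expvars = "depth"
  )
  parts <- split_binary_gaussian(s, "cpue")
  expect_equal(parts$binary, c(0L, 1L, 0L, 1L))
  expect_equal(parts$positive$cpue, c(log(2), 1))
  # exponentiating recovers the positive responses exactly
  expect_identical(exp(parts$positive$cpue), c(2, exp(1)))

  s1 <- as_samples(data.frame(latitude = 1, longitude = 1, depth = 1,
                              cpue = 5), resvars = "cpue", expvars = "depth")
  p1 <- split_binary_gaussian(s1, "cpue")
  expect_equal(p1$binary, 1L)
  expect_equal(p1$positive$cpue, log(5))

  s0 <- as_samples(data.frame(latitude = 1:2, longitude = 1:2, depth = 1:2,
                              cpue = c(0, 0)),
                   resvars = "cpue", expvars = "depth")
  expect_error(split_binary_gaussian(s0, "cpue"), "zero everywhere")
})

test_that("bfcheck reports the minimal feasible bag fraction per component", {
  s <- as_samples(
    data.frame(latitude = 1:100, longitude = 1:100, depth = 1:100,
               cpue = c(rep(0, 79), rep(1, 21))),
    resvars = "cpue", expvars = "depth"
  )
  res <- bfcheck(s, "cpue", min_train_rows = 21)
  expect_equal(res$bf_min[res$component == "binary"], 0.21)
  expect_equal(res$bf_min[res$component == "gaussian"], 1.00)
  expect_true(all(res$feasible))

  s2 <- as_samples(
    data.frame(latitude = 1:100, longitude = 1:100, depth = 1:100,
               cpue = c(rep(0, 80), rep(1, 20))),
    resvars = "cpue", expvars = "depth"
  )
  res2 <- bfcheck(s2, "cpue", min_train_rows = 21)
  expect_false(res2$feasible[res2$component == "gaussian"])
  expect_true(is.na(res2$bf_min[res2$component == "gaussian"]))
})
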