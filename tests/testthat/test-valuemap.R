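test_that("importance scaling is unit-max per species with ratios as
           weights", {
  good <- tibble::tibble(sp1 = c(2, 4), sp2 = c(1, 10))
  sc <- scale_importance(good, ratios = c(1, 1))
  expect_equal(sc$sp1, c(0.5, 1))
  expect_equal(sc$sp2, c(0.1, 1))

  # doubling a ratio leaves the unit-max vector unchanged...
  sc2 <- scale_importance(good, ratios = c(2, 1))
  expect_equal(sc2$sp1, sc$sp1)
  # ...but doubles that species' weight in a ratio-weighted sum
  r <- attr(sc2, "ratios")
  expect_equal(r[["sp1"]] * sc2$sp1 + r[["sp2"]] * sc2$sp2,
               2 * sc$sp1 + sc$sp2)

  expect_warning(z <- scale_importance(tibble::tibble(sp = c(0, 0))),
                 "zero everywhere")
  expect_equal(z$sp, c(0, 0))
  expect_error(scale_importance(good, ratios = 1), "2 species")
})

test_that("the combined metric hits its endpoints exactly and averages in
           between", {
  good <- c(0, 1, 0.5)
  bad <- c(10, 0, 5)  # max effort 10
  m <- combined_metric(good, bad)
  expect_identical(m[1], 0)    # max effort, no abundance
  expect_identical(m[2], 1)    # no effort, max abundance
  expect_identical(m[3], 0.5)  # mid abundance, half-of-max effort
  expect_true(all(m >= 0 & m <= 1))
})

test_that("cell orderings follow each scheme with deterministic ties", {
  data <- tibble::tibble(
    latitude = 1:3, longitude = 1:3,
    sp = c(3, 1, 2), effort = c(5, 0, 2), cons = c(1, 3, 2)
  )
  expect_equal(order_cells(data, "sp", "biomass"), c(1L, 3L, 2L))
  expect_equal(order_cells(data, "sp", "effort"), c(2L, 3L, 1L))
  expect_equal(order_cells(data, "sp", "conservation", conserve = "cons"),
               c(2L, 3L, 1L))
  expect_error(order_cells(data, "sp", "conservation"), "conservation")

  # constant stressor: combination ranking collapses to biomass ranking
  data$effort <- 4
  expect_equal(order_cells(data, "sp", "combination"),
               order_cells(data, "sp", "biomass"))

  # effort ties break by descending abundance
  data2 <- tibble::tibble(latitude = 1:3, longitude = 1:3,
                          sp = c(1, 5, 3), effort = c(2, 2, 0))
  expect_equal(order_cells(data2, "sp", "effort"), c(3L, 2L, 1L))
})

test_that("closures accumulate ranked cells until the biomass target", {
  # abundances already in biomass order
  expect_equal(build_closure(1:4, c(10, 5, 3, 2), 12), c(1L, 2L))
  expect_equal(build_closure(1:4, c(10, 5, 3, 2), 0), integer(0))
  expect_equal(build_closure(1:4, c(10, 5, 3, 2), 20), 1:4)
  expect_error(build_closure(1:4, c(10, 5, 3, 2), 21), "unattainable")
  # greedy minimality at the stopping cell
  members <- build_closure(1:4, c(10, 5, 3, 2), 12)
  expect_lt(sum(c(10, 5, 3, 2)[head(members, -1)]), 12)
})

test_that("the cascade matches a hand-computed two-species toy and the
           brute-force oracle", {
  # 6 cells, biomass sort, two species
  data <- tibble::tibble(
    latitude = 1:6, longitude = rep(0, 6),
    sp1 = c(10, 8, 1, 1, 0, 0),
    sp2 = c(0, 1, 1, 6, 8, 4),
    effort = c(1, 1, 1, 1, 1, 1)
  )
  spec <- closure_spec(species = c("sp1", "sp2"), hrmsy = c(0.2, 0.5),
                       scheme = "biomass")
  plan <- cascade_closures(data, spec)
  # sp1: target 0.8 * 20 = 16 -> cells 1, 2 (cumsum 18)
  # sp2: target 0.5 * 20 = 10; credited 1 (cell 2); adds cells 5 (8), 4 (6)
  expect_equal(sort(which(plan$cells$member)), c(1L, 2L, 4L, 5L))
  expect_equal(plan$cells$adder[c(1, 2)], c("sp1", "sp1"))
  expect_equal(plan$cells$adder[c(4, 5)], c("sp2", "sp2"))
  st <- plan$species_stats
  expect_equal(st$bpa_target, c(16, 10))
  expect_equal(st$credited_biomass, c(0, 1))
  expect_gte(st$protected_at_pass[1], st$bpa_target[1])
  expect_gte(st$protected_at_pass[2], st$bpa_target[2])

  # brute-force oracle agreement on random 6-12 cell instances
  for (seed in 1:20) {
    inst <- toy_dst_instance(seed + 100, n_cells = sample(6:12, 1),
                             n_species = 2)
    for (scheme in c("biomass", "effort")) {
      spec2 <- closure_spec(inst$spec$species, inst$spec$hrmsy,
                            scheme = scheme)
      plan2 <- cascade_closures(inst$data, spec2)
      oracle <- brute_force_cascade(inst$data, inst$spec$species,
                                    inst$spec$hrmsy, scheme = scheme)
      expect_equal(plan2$cells$member, oracle$member)
      expect_equal(plan2$cells$adder, oracle$adder)
    }
  }
})

test_that("full prior coverage means a later species adds no cells", {
  data <- tibble::tibble(
    latitude = 1:4, longitude = rep(0, 4),
    sp1 = c(10, 10, 0, 0), sp2 = c(5, 5, 0.1, 0),
    effort = rep(1, 4)
  )
  spec <- closure_spec(species = c("sp1", "sp2"), hrmsy = c(0.1, 0.5),
                       scheme = "biomass")
  plan <- cascade_closures(data, spec)
  st <- plan$species_stats
  expect_equal(st$cells_added[2], 0)
  expect_gte(st$credited_biomass[2], st$bpa_target[2])
})

test_that("the four-species harvest-rate vector of the reference fishery is
           accepted", {
  inst <- toy_dst_instance(7, n_cells = 50, n_species = 4)
  spec <- closure_spec(inst$spec$species,
                       hrmsy = c(0.08, 0.14, 0.08, 0.15),
                       scheme = "combination")
  plan <- cascade_closures(inst$data, spec)
  expect_true(all(plan$species_stats$protected_final >=
                    plan$species_stats$bpa_target - 1e-9))
})

test_that("effort overlap arithmetic and its degenerate legend", {
  bad <- c(2, 3, 1, 4)
  expect_equal(effort_overlap(c(1, 2), bad), 50)
  expect_equal(effort_overlap(integer(0), bad), 0)
  expect_equal(effort_overlap(1:4, bad), 100)
  und <- effort_overlap(1:2, c(0, 0))
  expect_true(is.na(und))
  expect_equal(attr(und, "legend"), "no effort data")
})

test_that("the cascade is deterministic and attribution partitions the
           closure", {
  inst <- toy_dst_instance(11)
  p1 <- cascade_closures(inst$data, inst$spec)
  p2 <- cascade_closures(inst$data, inst$spec)
  expect_identical(p1$cells, p2$cells)
  expect_identical(p1$species_stats, p2$species_stats)
  # adder is defined exactly on the member set
  expect_identical(!is.na(p1$cells$adder), p1$cells$member)
})
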