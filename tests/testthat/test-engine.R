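test_that("zero years echoes the initial state with no fluxes", {
  sim <- simulate_forest(years = 0, area_ha = 0.04, seed = 1)
  expect_equal(nrow(sim), 0)
  expect_s3_class(sim, "forest_simulation")
})

test_that("runs are bit-reproducible for a given seed", {
  a <- simulate_forest(years = 60, area_ha = 0.16, replicates = 2, seed = 42)
  b <- simulate_forest(years = 60, area_ha = 0.16, replicates = 2, seed = 42)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(attr(a, "by_pft"), attr(b, "by_pft"))
  expect_identical(attr(a, "final_trees"), attr(b, "final_trees"))
  c_run <- simulate_forest(years = 60, area_ha = 0.16, replicates = 2,
                           seed = 43)
  expect_false(identical(as.data.frame(a), as.data.frame(c_run)))
})

test_that("bare-ground succession builds biomass from recruits", {
  sim <- simulate_forest(config = kilimanjaro_config(), years = 150,
                         area_ha = 0.16, seed = 2)
  expect_gt(sim$agb[150], sim$agb[30])
  expect_gt(sim$agb[30], 0)
  expect_true(all(sim$agb >= 0))
  # stems appear before any reach the census threshold
  expect_gt(sim$stems_all[1], 0)
  expect_equal(sim$stems[1], 0)
})

test_that("the carbon ledger closes every simulated year", {
  sim <- simulate_forest(config = kilimanjaro_config(), years = 200,
                         area_ha = 0.16, seed = 3)
  stock <- sim$living_c + sim$deadwood_c + sim$soil_c
  delta <- diff(c(0, stock))  # pools start empty on bare ground
  expect_equal(delta, sim$gpp - sim$ra - sim$rh + sim$seed_influx,
               tolerance = 1e-9)
  # the external seed influx is a negligible flux at stand scale
  expect_lt(max(sim$seed_influx), 0.01)
  expect_equal(sim$nee, sim$gpp - sim$ra - sim$rh, tolerance = 1e-12)
  expect_equal(sim$npp, sim$gpp - sim$ra, tolerance = 1e-12)
  expect_equal(sim$total_c, stock, tolerance = 1e-12)
})

test_that("per-PFT records sum to the stand totals", {
  sim <- simulate_forest(config = kilimanjaro_config(), years = 120,
                         area_ha = 0.16, seed = 4)
  bp <- attr(sim, "by_pft")
  sums <- bp |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(agb10 = sum(agb10), basal_area = sum(basal_area),
                     stems = sum(stems))
  expect_equal(sums$agb10, sim$agb10, tolerance = 1e-9)
  expect_equal(sums$basal_area, sim$basal_area, tolerance = 1e-9)
  expect_equal(sums$stems, sim$stems, tolerance = 1e-9)
  # living carbon tracks standing biomass through the carbon fraction
  expect_equal(sim$living_c, attr(sim, "config")$odm_to_c * sim$agb,
               tolerance = 1e-9)
})

test_that("a census-initialised run starts at the inventory's structure", {
  census <- generate_census(seed = 5)
  asn <- assign_pft(generate_traits(seed = 5))
  sim <- simulate_forest(config = kilimanjaro_config(), years = 1,
                         area_ha = 0.25, seed = 6, initial = "census",
                         census = census, assignment = asn)
  expect_equal(sim$stems[1], 93 / 0.24, tolerance = 0.15)
  expect_error(simulate_forest(years = 1, initial = "census"),
               "census")
})

test_that("equilibrium statistics summarise a window correctly", {
  # constant synthetic trajectory: mean is the constant, range is zero
  sim <- simulate_forest(years = 0, area_ha = 0.04, seed = 1)
  const <- tibble::tibble(replicate = rep(1:2, each = 50),
                          year = rep(1:50, 2), x = 7)
  class(const) <- class(sim)
  es <- equilibrium_stats(const, c(10, 40))
  expect_equal(es$mean[es$variable == "x"], 7)
  expect_equal(es$min[es$variable == "x"], 7)
  expect_equal(es$max[es$variable == "x"], 7)
  expect_equal(es$rep_sd[es$variable == "x"], 0)

  # seeded stochastic series: the window mean equals direct recomputation
  set.seed(7)
  ar <- tibble::tibble(replicate = 1, year = 1:200,
                       x = as.numeric(arima.sim(list(ar = 0.5), 200)))
  class(ar) <- class(sim)
  es2 <- equilibrium_stats(ar, c(50, 150))
  expect_equal(es2$mean[es2$variable == "x"],
               mean(ar$x[ar$year >= 50 & ar$year <= 150]))
  expect_error(equilibrium_stats(ar, c(500, 600)), "outside")
})

test_that("comparison to field targets reports signed relative differences", {
  p <- pft_parameters()
  asn <- assign_pft(generate_traits(seed = 1), p)
  targets <- field_statistics(generate_census(seed = 1), asn, p)
  # build stats that match the targets exactly: all differences are zero
  stats <- dplyr::bind_rows(
    tibble::tibble(variable = c("agb10", "basal_area", "stems"),
                   pft = NA_integer_,
                   mean = c(targets$total$agb, targets$total$basal_area,
                            targets$total$stems)),
    tibble::tibble(variable = "agb10", pft = targets$by_pft$pft,
                   mean = targets$by_pft$agb))
  cmp <- compare_to_field(stats, targets)
  expect_true(all(abs(cmp$diff_pct[!is.na(cmp$diff_pct)]) < 1e-12))
})

test_that("size distributions bin stems in 10-cm classes", {
  toy <- tibble::tibble(species = "x",
                        dbh_cm = c(12, 15, 25, 31, 31, 155))
  sd_tbl <- size_distribution(toy, plot_area_m2 = 1e4)
  expect_equal(sd_tbl$stems[sd_tbl$dbh_lower_cm == 10], 2)
  expect_equal(sd_tbl$stems[sd_tbl$dbh_lower_cm == 20], 1)
  expect_equal(sd_tbl$stems[sd_tbl$dbh_lower_cm == 30], 2)
  expect_equal(sd_tbl$stems[sd_tbl$dbh_lower_cm == 150], 1)
  expect_equal(sum(sd_tbl$stems), 6)
})

test_that("plot and broom methods return the expected object types", {
  sim <- simulate_forest(config = kilimanjaro_config(), years = 40,
                         area_ha = 0.16, replicates = 1, seed = 8)
  expect_s3_class(autoplot(sim, "structure"), "ggplot")
  expect_s3_class(autoplot(sim, "nee"), "ggplot")
  expect_s3_class(plot_size_distribution(sim, window = c(20, 40)), "ggplot")
  expect_s3_class(plot_lai_profile(sim, window = c(20, 40)), "ggplot")
  g <- glance(sim, window = c(20, 40))
  expect_equal(nrow(g), 1)
  expect_true(all(c("agb", "gpp", "nee") %in% names(g)))
  td <- tidy(sim)
  expect_true(all(c("year", "pft", "variable", "value") %in% names(td)))
})
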