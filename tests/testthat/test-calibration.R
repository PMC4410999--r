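make_targets <- function(by_pft_agb, params = pft_parameters()) {
  structure(list(
    by_pft = tibble::tibble(pft = params$pft, agb = by_pft_agb,
                            basal_area = 0, stems = 0),
    total = tibble::tibble(agb = sum(by_pft_agb), basal_area = 0, stems = 0),
    size_distribution = NULL, upscaling_factor = 4),
    class = "field_targets")
}

test_that("the MSE objective is zero iff simulated equals observed", {
  # equal weights, two components off by +2 and -2: MSE = 4
  expect_equal(gapforest:::mse_components(c(12, 8), c(10, 10)), 4)
  expect_equal(gapforest:::mse_components(c(10, 10), c(10, 10)), 0)
  expect_gt(gapforest:::mse_components(c(10, 10.001), c(10, 10)), 0)
})

test_that("the simulation objective vanishes on self-generated targets", {
  p <- pft_parameters()
  cfg <- kilimanjaro_config()
  sim <- simulate_forest(p, cfg, years = 80, area_ha = 0.16, replicates = 2,
                         seed = 77)
  es <- equilibrium_stats(sim, c(40, 80))
  agb_pft <- es$mean[es$variable == "agb10" & !is.na(es$pft)]
  targets <- make_targets(agb_pft, p)
  # same settings and seed reproduce the same equilibrium: exact zero
  obj <- calibration_objective(p, targets, cfg, years = 80,
                               window = c(40, 80), replicates = 2,
                               area_ha = 0.16, seed = 77)
  expect_equal(obj, 0, tolerance = 1e-12)
  # a perturbed parameter set does not
  p2 <- p
  p2$m_base[1] <- p$m_base[1] * 3
  expect_gt(calibration_objective(p2, targets, cfg, years = 80,
                                  window = c(40, 80), replicates = 2,
                                  area_ha = 0.16, seed = 77), 0)
})

test_that("free-parameter application targets one PFT or all", {
  p <- pft_parameters()
  free <- tibble::tibble(parameter = c("m_base", "pmax"),
                         pft = c(1L, NA), lower = 0, upper = 1)
  p2 <- gapforest:::apply_free_values(p, free, c(0.5, 7))
  expect_equal(p2$m_base[1], 0.5)
  expect_equal(p2$m_base[-1], p$m_base[-1])
  expect_equal(p2$pmax, rep(7, 6))
  bad <- tibble::tibble(parameter = "nope", pft = NA, lower = 0, upper = 1)
  expect_error(gapforest:::apply_free_values(p, bad, 1), "unknown")
})

test_that("the search stays in bounds, logs every evaluation and is
           reproducible", {
  p <- pft_parameters()
  cfg <- kilimanjaro_config()
  targets <- make_targets(c(300, 30, 12, 2, 3, 0.5), p)
  free <- tibble::tibble(parameter = "m_base", pft = 1L,
                         lower = 0.004, upper = 0.008)
  cal <- calibrate_forest(targets, free, p, cfg, n_evaluations = 6,
                          years = 60, window = c(30, 60), replicates = 1,
                          area_ha = 0.16, seed = 10)
  expect_equal(nrow(cal$ledger), 6)
  expect_true(all(cal$ledger$m_base_pft1 >= 0.004 &
                    cal$ledger$m_base_pft1 <= 0.008))
  expect_equal(cal$best$mse, min(cal$ledger$mse))
  expect_equal(cal$best_params$m_base[1], cal$best$m_base_pft1)

  cal2 <- calibrate_forest(targets, free, p, cfg, n_evaluations = 6,
                           years = 60, window = c(30, 60), replicates = 1,
                           area_ha = 0.16, seed = 10)
  expect_identical(cal$ledger, cal2$ledger)
  expect_error(calibrate_forest(targets, free, p, cfg, n_evaluations = 0),
               "n_evaluations")

  expect_s3_class(autoplot(cal), "ggplot")
  expect_identical(tidy(cal), cal$ledger)
  expect_equal(glance(cal)$n_evaluations, 6)
})

test_that("inverse parameterization recovers targets generated by the
           model itself", {
  p_true <- pft_parameters()
  p_true$m_base[1] <- 0.0075  # the 'unknown' mortality to recover
  cfg <- kilimanjaro_config()
  sim <- simulate_forest(p_true, cfg, years = 220, area_ha = 0.16,
                         replicates = 2, seed = 21)
  es <- equilibrium_stats(sim, c(120, 220))
  targets <- make_targets(es$mean[es$variable == "agb10" & !is.na(es$pft)],
                          p_true)

  free <- tibble::tibble(parameter = "m_base", pft = 1L,
                         lower = 0.004, upper = 0.012)
  cal <- calibrate_forest(targets, free, pft_parameters(), cfg,
                          n_evaluations = 10, years = 220,
                          window = c(120, 220), replicates = 1,
                          area_ha = 0.16, seed = 22)
  # the recovered optimum does at least as well as the generating value
  # under the same evaluation settings
  obj_true <- calibration_objective(p_true, targets, cfg, years = 220,
                                    window = c(120, 220), replicates = 1,
                                    area_ha = 0.16, seed = 22)
  expect_lte(cal$best$mse, obj_true * 1.5 + 1)
  # and the recovered equilibrium biomass is close to the target biomass
  resim <- simulate_forest(cal$best_params, cfg, years = 220,
                           area_ha = 0.16, replicates = 2, seed = 23)
  es2 <- equilibrium_stats(resim, c(120, 220))
  agb_hat <- es2$mean[es2$variable == "agb10" & is.na(es2$pft)]
  expect_lt(abs(agb_hat - targets$total$agb) / targets$total$agb, 0.25)
})
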