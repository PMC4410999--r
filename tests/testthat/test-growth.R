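test_that("height allometry saturates at h1 and starts at slope h0", {
  p <- pft_parameters()
  expect_equal(height_from_diameter(0, 1, p), 0)
  expect_equal(height_from_diameter(1e6, 1, p), p$h1[1], tolerance = 1e-3)
  d <- 1e-9
  expect_equal(height_from_diameter(d, 2, p) / d, p$h0[2], tolerance = 1e-4)
  expect_true(all(diff(height_from_diameter(seq(0, 2, 0.05), 1, p)) > 0))
})

test_that("height-diameter fit recovers known coefficients within 5%", {
  set.seed(42)
  h0_true <- 140
  h1_true <- 45
  d <- runif(300, 0.1, 1.3)
  h <- d / (1 / h0_true + d / h1_true) * rlnorm(300, 0, 0.05)
  fit <- fit_height_allometry(tibble::tibble(dbh_m = d, height_m = h))
  expect_lt(abs(fit$h0 - h0_true) / h0_true, 0.05)
  expect_lt(abs(fit$h1 - h1_true) / h1_true, 0.05)
})

test_that("crown gross production matches a fine quadrature of the
           saturating light response through the crown", {
  p <- pft_parameters()
  cfg <- kilimanjaro_config()
  for (k_pft in c(1L, 4L)) {
    for (light in c(1, 0.3, 0.05)) {
      got <- tree_gross_production(50, k_pft, light, p, cfg)
      # independent oracle: numeric integration over 1e4 leaf sub-layers
      ai <- p$alpha[k_pft] * cfg$i0 * light
      L <- p$lai_tree[k_pft]
      l <- (seq_len(1e4) - 0.5) * L / 1e4
      leaf_rate <- p$pmax[k_pft] * ai * exp(-cfg$k * l) /
        (p$pmax[k_pft] + ai * exp(-cfg$k * l))
      oracle <- 50 * sum(leaf_rate) * (L / 1e4) * cfg$c_odm
      expect_equal(got, oracle, tolerance = 1e-6)
    }
  }
})

test_that("gross production behaves at the limits", {
  p <- pft_parameters()
  cfg <- kilimanjaro_config()
  expect_equal(tree_gross_production(50, 1, 0, p, cfg), 0)
  light <- seq(0, 1, 0.1)
  expect_true(all(diff(tree_gross_production(50, 1, light, p, cfg)) > 0))
  # pmax -> Inf: light response becomes linear; closed form tends to
  # alpha I (1 - exp(-kL)) / k per unit crown area
  p_inf <- p
  p_inf$pmax[1] <- 1e9
  ai <- p$alpha[1] * cfg$i0
  lin <- 50 * ai * (1 - exp(-cfg$k * p$lai_tree[1])) / cfg$k * cfg$c_odm
  expect_equal(tree_gross_production(50, 1, 1, p_inf, cfg), lin,
               tolerance = 1e-6)
  expect_error(tree_gross_production(50, 1, 1.5, p, cfg), "incident_light")
})

test_that("biomass increment implements the carbon balance with the size
           limiter", {
  p <- pft_parameters()
  cfg <- kilimanjaro_config()
  b <- 1.2
  # compensation point: gpp equal to maintenance leaves biomass unchanged
  inc <- biomass_increment(b, 0.4, 1, gpp = p$r_m[1] * b, p, cfg)
  expect_equal(inc$npp, 0, tolerance = 1e-12)
  expect_equal(inc$increment, 0, tolerance = 1e-12)
  # at d_max growth stops regardless of light; production turns to litter
  inc2 <- biomass_increment(b, p$d_max[1], 1, gpp = 10, p, cfg)
  expect_equal(inc2$increment, 0, tolerance = 1e-12)
  expect_equal(inc2$litter, inc2$npp, tolerance = 1e-12)
  # hand evaluation for a sunlit sapling
  gpp <- 0.05
  npp_hand <- (1 - p$r_g[2]) * (gpp - p$r_m[2] * 0.01)
  g_hand <- 1 - (0.05 / p$d_max[2])^cfg$gamma
  inc3 <- biomass_increment(0.01, 0.05, 2, gpp, p, cfg)
  expect_equal(inc3$increment, npp_hand * g_hand, tolerance = 1e-12)
  # shaded tree with a negative balance shrinks, sheds no litter
  inc4 <- biomass_increment(b, 0.4, 1, gpp = 0, p, cfg)
  expect_lt(inc4$increment, 0)
  expect_equal(inc4$litter, 0)
  # monotone: more light (higher gpp) never decreases the increment
  incs <- biomass_increment(rep(b, 5), rep(0.4, 5), 1,
                            gpp = seq(0, 0.5, length.out = 5), p, cfg)
  expect_true(all(diff(incs$increment) >= 0))
})

test_that("the biomass allometry inverts exactly", {
  p <- pft_parameters()
  d <- c(0.01, 0.05, 0.3, 0.8, 1.4)
  for (k in c(1L, 3L, 6L)) {
    dd <- pmin(d, p$d_max[k] * 0.99)
    b <- tree_agb(dd, k, p)
    # round trip b -> d -> b
    d_back <- diameter_from_agb(b, k, p)
    expect_equal(d_back, dd, tolerance = 1e-8)
    expect_equal(tree_agb(d_back, k, p), b, tolerance = 1e-8)
  }
  expect_equal(diameter_from_agb(0, 1, p), 0)
  # beyond the attainable biomass the diameter pins at d_max
  b_over <- tree_agb(p$d_max[2], 2, p) * 2
  expect_equal(diameter_from_agb(b_over, 2, p), p$d_max[2])

  geo <- update_geometry(0.3, 1, tree_agb(0.3, 1, p), p)
  expect_equal(geo$d, 0.3, tolerance = 1e-9)
})

test_that("an isolated tree in full light grows to its carbon-balance
           fixed point", {
  p <- pft_parameters()
  cfg <- kilimanjaro_config()
  d <- 0.02
  b <- tree_agb(d, 2, p)
  for (i in 1:600) {
    ca <- tree_geometry(d, 2, p)$crown_area
    gpp <- tree_gross_production(ca, 2, 1, p, cfg)
    inc <- biomass_increment(b, d, 2, gpp, p, cfg)
    b_new <- b + inc$increment
    expect_gte(b_new, b)  # monotone approach in full light
    b <- b_new
    d <- diameter_from_agb(b, 2, p, d_start = d)
  }
  # fixed point: either growth stalled by the size cap or npp ~ 0
  ca <- tree_geometry(d, 2, p)$crown_area
  gpp <- tree_gross_production(ca, 2, 1, p, cfg)
  inc <- biomass_increment(b, d, 2, gpp, p, cfg)
  expect_lt(abs(inc$increment) / b, 1e-3)
})
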