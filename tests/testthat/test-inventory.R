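test_that("read_census validates, filters the 10-cm threshold and reports", {
  f <- withr::local_tempfile(fileext = ".csv")
  census <- generate_census(seed = 3)
  readr::write_csv(census, f)
  got <- read_census(f)
  expect_equal(nrow(got), 93)
  expect_equal(attr(got, "n_excluded"), 0L)

  small <- census[1:5, ]
  small$dbh_cm[3] <- 5
  readr::write_csv(small, f)
  expect_message(got <- read_census(f), "1 stem")
  expect_equal(nrow(got), 4)
  expect_equal(attr(got, "n_excluded"), 1L)

  readr::write_csv(census[0, ], f)
  expect_warning(got <- read_census(f), "empty")
  expect_equal(nrow(got), 0)

  readr::write_csv(dplyr::rename(census, dbh = dbh_cm), f)
  expect_error(read_census(f), "dbh_cm")

  bad <- census
  bad$dbh_cm <- as.character(bad$dbh_cm)
  bad$dbh_cm[7] <- "big"
  readr::write_csv(bad, f)
  expect_error(read_census(f), "row")
})

test_that("shipped example census reads cleanly", {
  f <- system.file("extdata", "synthetic_census_flm3.csv",
                   package = "gapforest")
  census <- read_census(f)
  expect_equal(nrow(census), 93)
  expect_equal(length(unique(census$species)), 16)
})

test_that("trait-based PFT assignment is total, deterministic and matches
           the height x shade-tolerance scheme", {
  traits <- generate_traits(seed = 5)
  asn <- assign_pft(traits)
  expect_setequal(asn$species, traits$species)
  expect_equal(asn$pft[match(traits$species, asn$species)], traits$true_pft)

  # permuting rows never changes the mapping
  perm <- traits[sample.int(nrow(traits)), ]
  asn2 <- assign_pft(perm)
  expect_equal(asn2[order(asn2$species), ], asn[order(asn$species), ])

  # idempotent / deterministic
  expect_identical(assign_pft(traits), asn)
})

test_that("exemplar species map to their published functional types when the
           expert light class is given", {
  traits <- tibble::tibble(
    species = c("Strombosia scheffleri", "Heinsenia diervilleoides",
                "Ficus sur", "Polyscias albersiana",
                "Leptonychia usambarensis", "Cyathea manniana"),
    max_height_m = c(40, 25, 25, 25, 12, 12),
    sdmc = 0.45, leaf_n = 24,
    light_class_override = c("tolerant", "tolerant", "intermediate",
                             "intolerant", "tolerant", "intolerant"))
  asn <- assign_pft(traits)
  expect_equal(asn$pft[match(traits$species, asn$species)], 1:6)
})

test_that("height-class boundaries are half-open: exactly 16 m is 16-33", {
  traits <- tibble::tibble(
    species = c("a", "b", "c"), max_height_m = c(16, 33, 15.999),
    sdmc = c(0.55, 0.55, 0.35), leaf_n = c(18, 18, 30),
    light_class_override = c("tolerant", "tolerant", "intolerant"))
  asn <- assign_pft(traits)
  expect_equal(asn$height_class[match(c("a", "b", "c"), asn$species)],
               c("16-33", ">33", "<16"))
  expect_equal(asn$pft[match(c("a", "b", "c"), asn$species)], c(2L, 1L, 6L))
})

test_that("unassignable species raise a listing error", {
  traits <- tibble::tibble(species = "x", max_height_m = 40,
                           sdmc = 0.45, leaf_n = 24,
                           light_class_override = "intolerant")
  # no PFT for tall shade-intolerant at this site
  expect_error(assign_pft(traits), "x")
})

test_that("tree_agb follows B = (pi/4) d^2 h f rho", {
  p <- toy_params(h1 = 30, f = 0.25, rho = 0.6)
  expect_equal(tree_agb(0, 1, p), 0)
  # hand evaluation: (pi/4) * 0.25 * 30 * 0.25 * 0.6
  expect_equal(tree_agb(0.5, 1, p), (pi / 4) * 0.25 * 30 * 0.25 * 0.6,
               tolerance = 1e-6)
  # linear in wood density
  p2 <- p
  p2$rho <- p$rho * 2
  expect_equal(tree_agb(0.5, 1, p2), 2 * tree_agb(0.5, 1, p))
  # monotone increasing in d for every PFT
  d <- seq(0.01, 1.5, length.out = 60)
  for (k in pft_parameters()$pft) {
    expect_true(all(diff(tree_agb(d, k)) > 0))
  }
  expect_error(tree_agb(0.2, 99), "unknown pft")
})

test_that("field statistics upscale linearly and add up exactly", {
  p <- pft_parameters()
  asn <- assign_pft(generate_traits(seed = 1), p)

  one <- tibble::tibble(species = "Strombosia scheffleri", dbh_cm = 20)
  fs <- field_statistics(one, asn, p)
  expect_equal(fs$total$basal_area, 4 * (pi / 4) * 0.04, tolerance = 1e-12)
  expect_equal(fs$total$stems, 4)

  census <- generate_census(seed = 2)
  fs <- field_statistics(census, asn, p)
  expect_equal(fs$total$stems, 93 * 4)
  # per-PFT additivity
  expect_equal(sum(fs$by_pft$agb), fs$total$agb, tolerance = 1e-12)
  expect_equal(sum(fs$by_pft$basal_area), fs$total$basal_area,
               tolerance = 1e-12)
  expect_equal(sum(fs$size_distribution$stems), fs$total$stems)

  # duplicating the census on a doubled plot leaves per-ha values unchanged
  fs2 <- field_statistics(dplyr::bind_rows(census, census), asn, p,
                          plot_area_m2 = 5000)
  expect_equal(fs2$total, fs$total, tolerance = 1e-12)
  expect_equal(fs2$by_pft, fs$by_pft, tolerance = 1e-12)

  empty <- census[0, ]
  fs0 <- field_statistics(empty, asn, p)
  expect_true(all(fs0$total == 0))
  expect_error(field_statistics(census, asn, p, plot_area_m2 = 0), "area")

  td <- tidy(fs)
  expect_equal(nrow(td), 7)
})
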