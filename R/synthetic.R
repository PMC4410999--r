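#' Species pool emulating the FLM3 lower montane inventory
#'
#' A 16-species pool with the stand's printed dominance structure: the four
#' dominants hold 36%, 24%, 6% and 5% of stems and the remaining 29% is
#' spread over twelve rarer species by a geometric series (ratio 0.75).
#' Each species carries its PFT, relative abundance and an upper diameter
#' bound (tall emergents reach large diameters, understory treelets do not).
#'
#' @return A tibble `species, pft, abundance, d_max_m`.
#' @export
flm3_species <- function() {
  rare_ab <- 0.29 * 0.25 / (1 - 0.75^12) * 0.75^(0:11)
  tibble::tibble(
    species = c(
      "Heinsenia diervilleoides", "Strombosia scheffleri",
      "Entandophrangma excelsum", "Garcinia tansaniensis",
      "Leptonychia usambarensis", "Ocotea usambarensis",
      "Cyathea manniana", "Tabernaemontana stapfiana",
      "Polyscias albersiana", "Ficus sur", "Syzygium guineense",
      "Neoboutonia macrocalyx", "Rauvolfia caffra",
      "Albizia gummifera", "Macaranga kilimandscharica",
      "Vernonia auriculifera"),
    pft = c(2L, 1L, 1L, 2L,
            5L, 1L, 6L, 3L, 4L, 3L, 3L, 4L, 3L, 3L, 4L, 6L),
    abundance = c(0.36, 0.24, 0.06, 0.05, rare_ab),
    d_max_m = c(0.45, 1.48, 1.58, 0.45,
                0.32, 1.25, 0.22, 0.60, 0.50, 0.60, 0.60,
                0.50, 0.60, 0.60, 0.50, 0.22)
  )
}

#' Generate a synthetic stem census
#'
#' Builds an inventory table with the statistical structure of a 0.25-ha
#' lower montane old-growth plot: a fixed number of stems allocated to
#' species by their relative abundance (largest-remainder rounding, so the
#' dominance fractions are met exactly up to integer stems), stem diameters
#' from a decreasing truncated power law (systematic quantile sample within
#' species, truncated below at the 10-cm census threshold and above at the
#' species' diameter bound, so each generated inventory carries the stand's
#' size structure rather than an iid resample of it), heights from the PFT
#' height allometry with lognormal noise, and uniform stem positions.
#'
#' @param n_trees Number of stems (default 93).
#' @param species_pool Species table as from [flm3_species()]; its first
#'   `n_species` rows are used.
#' @param n_species Number of species to use from the pool.
#' @param exponent Power-law exponent of the diameter distribution (> 1).
#' @param min_dbh_cm Lower diameter truncation, cm.
#' @param plot Plot edge lengths, m (length-2 vector).
#' @param height_cv Lognormal sd of the multiplicative height noise.
#' @param params PFT parameter table (for the height allometry).
#' @param seed Random seed.
#' @return A census tibble `tree_id, species, dbh_cm, height_m,
#'   crown_diameter_m, x_m, y_m` with attribute `species_pool`.
#' @export
#' @examples
#' census <- generate_census(seed = 1)
#' nrow(census)  # 93
generate_census <- function(n_trees = 93,
                            species_pool = flm3_species(),
                            n_species = nrow(species_pool),
                            exponent = 1.3,
                            min_dbh_cm = 10,
                            plot = c(50, 50),
                            height_cv = 0.08,
                            params = pft_parameters(),
                            seed = NULL) {
  if (n_species > n_trees) {
    stop("more species than trees requested", call. = FALSE)
  }
  stopifnot(exponent > 1, n_species >= 1, length(plot) == 2)
  pool <- species_pool[seq_len(n_species), ]
  ab <- pool$abundance / sum(pool$abundance)
  if (!is.null(seed)) set.seed(seed)

  # largest-remainder allocation, every species present at least once
  n_i <- pmax(floor(ab * n_trees), 1)
  while (sum(n_i) > n_trees) {  # possible when rare species were raised to 1
    i <- which.max(n_i - ab * n_trees)
    n_i[i] <- n_i[i] - 1
  }
  rem <- ab * n_trees - n_i
  while (sum(n_i) < n_trees) {
    i <- which.max(rem)
    n_i[i] <- n_i[i] + 1
    rem[i] <- -Inf
  }

  dmin <- min_dbh_cm / 100
  rows <- purrr::pmap(
    list(pool$species, pool$pft, pool$d_max_m, n_i),
    function(sp, pft, dmax, n) {
      if (n == 0) return(NULL)
      # systematic quantile sample of the size law: one fixed inventory's
      # size structure, not an iid resample
      u <- (seq_len(n) - 0.5) / n
      d <- qtrunc_powerlaw(u, exponent, dmin, dmax)
      h <- height_from_diameter(d, pft, params) *
        stats::rlnorm(n, -height_cv^2 / 2, height_cv)
      tibble::tibble(species = sp, pft = pft, dbh_cm = d * 100, height_m = h)
    })
  census <- dplyr::bind_rows(rows)
  n <- nrow(census)
  pv <- param_vectors(params)
  census <- census |>
    dplyr::mutate(
      crown_diameter_m = pv$crown_d_ratio[.data$pft] * .data$dbh_cm / 100,
      x_m = stats::runif(n, 0, plot[1]),
      y_m = stats::runif(n, 0, plot[2])) |>
    dplyr::slice_sample(n = n) |>
    dplyr::mutate(tree_id = sprintf("t%03d", seq_len(n))) |>
    dplyr::select("tree_id", "species", "dbh_cm", "height_m",
                  "crown_diameter_m", "x_m", "y_m")
  attr(census, "species_pool") <- pool
  census
}

# inverse CDF of a power law with density ~ d^-a truncated to [dmin, dmax]
qtrunc_powerlaw <- function(u, a, dmin, dmax) {
  e <- 1 - a
  (dmin^e + u * (dmax^e - dmin^e))^(1 / e)
}

dbh_law_expected_bins <- function(breaks_cm, a, dmin, dmax) {
  # bin probabilities of the truncated power law (for distributional checks)
  cdf <- function(d) {
    d <- pmin(pmax(d, dmin), dmax)
    e <- 1 - a
    (d^e - dmin^e) / (dmax^e - dmin^e)
  }
  diff(cdf(breaks_cm / 100))
}

#' Generate a species trait table consistent with a PFT mapping
#'
#' Emits maximum height, stem dry matter content (SDMC) and leaf nitrogen
#' values such that the trait-based classifier ([assign_pft()]) reproduces a
#' requested species-to-PFT mapping: heights are drawn within the PFT's
#' height class and the two shade-tolerance traits are drawn from
#' well-separated class distributions (tolerant: high SDMC, low leaf N).
#' The requested mapping is retained as a `true_pft` column for testing.
#'
#' @param species Character vector of species names, or a species pool tibble
#'   with `species` and `pft` columns (default [flm3_species()]).
#' @param pft Requested PFT per species (ignored when `species` is a tibble).
#' @param params PFT parameter table.
#' @param seed Random seed.
#' @return A traits tibble `species, max_height_m, sdmc, leaf_n,
#'   light_class_override, true_pft` (override all `NA` by default).
#' @export
generate_traits <- function(species = flm3_species(), pft = NULL,
                            params = pft_parameters(), seed = NULL) {
  if (is.data.frame(species)) {
    pft <- species$pft
    species <- species$species
  }
  stopifnot(length(pft) == length(species))
  if (!is.null(seed)) set.seed(seed)
  idx <- match(pft, params$pft)
  hclass <- params$height_class[idx]
  lclass <- params$light_class[idx]
  n <- length(species)

  h_rng <- list("<16" = c(8, 15), "16-33" = c(18, 31), ">33" = c(34, 48))
  max_h <- vapply(hclass, function(hc)
    stats::runif(1, h_rng[[hc]][1], h_rng[[hc]][2]), numeric(1))

  sdmc_mu <- c(tolerant = 0.55, intermediate = 0.45, intolerant = 0.35)
  leafn_mu <- c(tolerant = 18, intermediate = 24, intolerant = 30)
  sdmc <- stats::rnorm(n, sdmc_mu[lclass], 0.015)
  leaf_n <- stats::rnorm(n, leafn_mu[lclass], 0.8)

  tibble::tibble(species = species, max_height_m = max_h,
                 sdmc = sdmc, leaf_n = leaf_n,
                 light_class_override = NA_character_,
                 true_pft = pft)
}
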