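#' Annual stochastic mortality
#'
#' Each tree dies with probability \eqn{1 - e^{-(m_{base} + m_{size} +
#' m_{stress})}} where \eqn{m_{size} = ms_0 e^{-ms_1 d}} elevates the
#' mortality of small stems, \eqn{m_{sen} = msen\,(d/d_{max})^8} raises the
#' mortality of senescent trees near their maximum diameter, and
#' \eqn{m_{stress}} scales with the tree's relative carbon deficit
#' (suppressed trees). A dying tree with diameter at
#' least `d_fall` falls with probability `p_fall` onto a uniformly chosen
#' neighbouring patch, killing each tree there with probability equal to the
#' faller's crown area over the patch area (gap creation).
#'
#' @param trees A tibble with columns `pft`, `d`, `b`, `patch` and optionally
#'   `stress` (relative carbon deficit in \[0,1\]) and `crown_area`.
#' @param params PFT parameter table.
#' @param neighbours Integer matrix (`n_patch` x 4) of von-Neumann neighbour
#'   patch ids (torus); a 1 x 4 matrix of 1s for a single patch.
#' @param patch_area Patch ground area, m^2.
#' @param rate_only If `TRUE`, return the per-tree annual mortality rates
#'   instead of drawing deaths.
#' @return A list with `dead` (logical vector over `trees`) and `events`, a
#'   tibble `tree, pft, d, biomass_lost, cause, fell, target_patch` (cause is
#'   `"mortality"` for the focal death or `"felled"` for collateral deaths).
#' @export
mortality_step <- function(trees, params = pft_parameters(),
                           neighbours = matrix(1L, 1, 4), patch_area = 400,
                           rate_only = FALSE) {
  pv <- param_vectors(params)
  n <- nrow(trees)
  stress <- if ("stress" %in% names(trees)) trees$stress else numeric(n)
  pft <- trees$pft
  rate <- pv$m_base[pft] + pv$ms0[pft] * exp(-pv$ms1[pft] * trees$d) +
    pv$m_stress[pft] * stress +
    pv$msen[pft] * (trees$d / pv$d_max[pft])^8
  if (rate_only) return(rate)
  p_die <- 1 - exp(-rate)
  dead <- stats::runif(n) < p_die
  cause <- rep("mortality", n)

  crown_area <- if ("crown_area" %in% names(trees)) trees$crown_area else
    tree_geometry(trees$d, pft, params, patch_area)$crown_area

  fallers <- which(dead & trees$d >= pv$d_fall[pft] &
                     stats::runif(n) < pv$p_fall[pft])
  fell <- logical(n)
  fell[fallers] <- TRUE
  target <- rep(NA_integer_, n)
  for (i in fallers) {
    tp <- neighbours[trees$patch[i], sample.int(4, 1)]
    target[i] <- tp
    victims <- which(trees$patch == tp & !dead)
    if (length(victims) > 0) {
      hit <- victims[stats::runif(length(victims)) <
                       crown_area[i] / patch_area]
      dead[hit] <- TRUE
      cause[hit] <- "felled"
    }
  }
  idx <- which(dead)
  events <- tibble::tibble(
    tree = idx, pft = pft[idx], d = trees$d[idx],
    biomass_lost = trees$b[idx], cause = cause[idx],
    fell = fell[idx], target_patch = target[idx])
  list(dead = dead, events = events)
}

#' Crowding mortality (crown-space competition)
#'
#' Within a patch, the summed crown projection area in any height layer
#' cannot exceed the patch area. Where it does, trees spanning the violated
#' layer are removed smallest-first until the constraint holds; no more
#' trees are removed than needed.
#'
#' @param trees A tibble with `d`, `pft`, `patch` (single patch or several).
#' @param params PFT parameter table.
#' @param patch_area Patch ground area, m^2.
#' @param config Global configuration (layer discretization).
#' @return Logical vector: `TRUE` for trees removed by crowding.
#' @export
crowding_mortality <- function(trees, params = pft_parameters(),
                               patch_area = 400, config = forest_config()) {
  pv <- param_vectors(params)
  geo <- tree_geometry(trees$d, trees$pft, params, patch_area)
  removed <- logical(nrow(trees))
  dz <- config$dz
  n_lay <- ceiling(config$max_height / dz)
  for (p in unique(trees$patch)) {
    in_p <- which(trees$patch == p)
    lay_top <- pmin(pmax(ceiling(geo$crown_top[in_p] / dz), 1), n_lay)
    lay_base <- pmin(pmax(floor(geo$crown_base[in_p] / dz) + 1, 1), lay_top)
    ca <- geo$crown_area[in_p]
    cca <- numeric(n_lay)
    for (j in seq_along(in_p)) {
      cca[lay_base[j]:lay_top[j]] <- cca[lay_base[j]:lay_top[j]] + ca[j]
    }
    alive <- rep(TRUE, length(in_p))
    while (max(cca) > patch_area) {
      worst <- which.max(cca)
      spanning <- which(alive & lay_base <= worst & lay_top >= worst)
      if (length(spanning) == 0) break
      v <- spanning[which.min(trees$d[in_p][spanning])]
      alive[v] <- FALSE
      cca[lay_base[v]:lay_top[v]] <- cca[lay_base[v]:lay_top[v]] - ca[v]
    }
    removed[in_p[!alive]] <- TRUE
  }
  removed
}

#' Annual light-gated recruitment
#'
#' For each PFT, a Poisson number of candidate recruits (`n_seed` per ha and
#' year, reaching 1 cm dbh) arrives on uniformly chosen patches; a candidate
#' establishes only where the relative light at the forest floor is at least
#' the PFT's establishment threshold `i_seed`. The recruitment pool is
#' constant: the simulated stand is treated as embedded in continuous
#' forest, with no parent-tree seed limitation.
#'
#' @param floor_light Vector of relative floor light per patch.
#' @param params PFT parameter table.
#' @param area_ha Simulated area in hectares.
#' @return A tibble of new trees: `pft, patch, d` (d = 0.01 m).
#' @export
recruitment_step <- function(floor_light, params = pft_parameters(),
                             area_ha = length(floor_light) * 400 / 1e4) {
  pv <- param_vectors(params)
  n_patch <- length(floor_light)
  out <- vector("list", pv$n_pft)
  for (k in seq_len(pv$n_pft)) {
    n_cand <- stats::rpois(1, pv$n_seed[k] * area_ha)
    if (n_cand == 0) next
    patch <- sample.int(n_patch, n_cand, replace = TRUE)
    ok <- floor_light[patch] >= pv$i_seed[k]
    if (any(ok)) {
      out[[k]] <- tibble::tibble(pft = pv$pft[k], patch = patch[ok],
                                 d = 0.01)
    }
  }
  dplyr::bind_rows(out)
}
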