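#' Run the individual-based forest gap simulation
#'
#' Simulates every tree on a grid of gap-scale patches (20 m x 20 m) in
#' annual steps. Within a year the processes run in the fixed order
#' light -> growth -> mortality (incl. tree falls and crown crowding) ->
#' recruitment -> carbon pools. Patch light climates follow Lambert-Beer
#' extinction through the per-patch leaf-area profile; tree growth follows
#' the individual carbon balance; mortality, tree falls and recruitment are
#' stochastic with separate RNG streams per process so runs are
#' bit-reproducible for a given seed and toggling one process does not shift
#' another's draws.
#'
#' @param params PFT parameter table ([pft_parameters()]).
#' @param config Global configuration ([forest_config()]).
#' @param years Number of simulated years.
#' @param area_ha Simulated stand area, ha (divided into whole patches).
#' @param replicates Number of independent replicate runs.
#' @param seed Master random seed.
#' @param initial `"bare_ground"` (succession from empty ground) or
#'   `"census"` (initialise from an inventory).
#' @param census,assignment Census tibble and species-to-PFT assignment,
#'   required for `initial = "census"`.
#' @return A tibble of class `forest_simulation` with one row per
#'   (replicate, year): stand totals (`agb` all trees, `agb10`,
#'   `basal_area`, `stems` and `stems_all` where the `10` suffix / `stems`
#'   use the census threshold dbh > 10 cm; t_odm/ha, m^2/ha, ha^-1), carbon
#'   fluxes in t_c ha^-1 yr^-1 (`gpp, ra, npp, mortality_flux, litter_flux,
#'   rh, nee`, plus `seed_influx`, the small external biomass arriving with
#'   recruits, which closes the mass balance exactly:
#'   annual change of `living_c + deadwood_c + soil_c` equals
#'   `gpp - ra - rh + seed_influx`), pools in t_c/ha
#'   (`living_c, deadwood_c, soil_c`), and LAI at
#'   0, 0.5 and 2 m. Attributes: `by_pft` (per-PFT annual records),
#'   `size_distribution` (annual 10-cm-bin stem counts), `lai_profile`
#'   (annual mean/min/max LAI by height), `final_trees` (tree list at the
#'   last year), plus the call's parameters.
#' @export
simulate_forest <- function(params = pft_parameters(),
                            config = forest_config(),
                            years = 1000, area_ha = 1, replicates = 1,
                            seed = 1,
                            initial = c("bare_ground", "census"),
                            census = NULL, assignment = NULL) {
  initial <- match.arg(initial)
  pv <- param_vectors(params)
  patch_area <- config$patch_size^2
  n_patch <- max(1L, round(area_ha * 1e4 / patch_area))
  area <- n_patch * patch_area / 1e4
  nb <- patch_neighbours(n_patch)

  init <- NULL
  if (initial == "census") {
    if (is.null(census) || is.null(assignment)) {
      stop("initial = 'census' requires census and assignment", call. = FALSE)
    }
    pft0 <- assignment$pft[match(census$species, assignment$species)]
    if (any(is.na(pft0))) stop("census species missing from assignment",
                               call. = FALSE)
    init <- list(pft = as.integer(pft0), d = census$dbh_cm / 100)
  }

  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1, replicates)
  runs <- lapply(seq_len(replicates), function(r) {
    run_trajectory(pv, config, years, n_patch, nb, patch_area, area,
                   rep_seeds[r], init)
  })

  totals <- dplyr::bind_rows(lapply(seq_len(replicates), function(r) {
    dplyr::mutate(runs[[r]]$totals, replicate = r, .before = 1)
  }))
  by_pft <- dplyr::bind_rows(lapply(seq_len(replicates), function(r) {
    dplyr::mutate(runs[[r]]$by_pft, replicate = r, .before = 1)
  }))
  size_dist <- dplyr::bind_rows(lapply(seq_len(replicates), function(r) {
    dplyr::mutate(runs[[r]]$size_dist, replicate = r, .before = 1)
  }))
  lai_profile <- dplyr::bind_rows(lapply(seq_len(replicates), function(r) {
    dplyr::mutate(runs[[r]]$lai_profile, replicate = r, .before = 1)
  }))
  final_trees <- dplyr::bind_rows(lapply(seq_len(replicates), function(r) {
    dplyr::mutate(runs[[r]]$final_trees, replicate = r, .before = 1)
  }))

  structure(totals,
            by_pft = by_pft, size_distribution = size_dist,
            lai_profile = lai_profile, final_trees = final_trees,
            params = params, config = config, area_ha = area,
            years = years, seed = seed,
            class = c("forest_simulation", class(totals)))
}

patch_neighbours <- function(n_patch) {
  ny <- max(1L, floor(sqrt(n_patch)))
  while (n_patch %% ny != 0) ny <- ny - 1L
  nx <- n_patch %/% ny
  p <- seq_len(n_patch) - 1L
  r <- p %/% nx
  cc <- p %% nx
  idx <- function(rr, ccc) ((rr %% ny) * nx + (ccc %% nx)) + 1L
  cbind(idx(r - 1, cc), idx(r + 1, cc), idx(r, cc - 1), idx(r, cc + 1))
}

# three independent RNG streams derived from one seed
make_streams <- function(seed, names = c("mortality", "fall", "recruitment")) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1, length(names))
  env <- new.env(parent = emptyenv())
  for (i in seq_along(names)) {
    set.seed(seeds[i])
    assign(names[i], get(".Random.seed", envir = globalenv()), envir = env)
  }
  env
}

with_stream <- function(streams, name, expr) {
  assign(".Random.seed", get(name, envir = streams), envir = globalenv())
  res <- expr
  assign(name, get(".Random.seed", envir = globalenv()), envir = streams)
  res
}

run_trajectory <- function(pv, config, years, n_patch, nb, patch_area, area,
                           seed, init = NULL) {
  streams <- make_streams(seed)
  n_pft <- pv$n_pft
  lai_heights <- seq(0, config$max_height - 2, by = 2)
  bin_lower <- seq(10, 150, by = 10)

  # state
  if (is.null(init)) {
    pft <- integer(0); d <- numeric(0); b <- numeric(0); stress <- numeric(0)
    patch <- integer(0)
  } else {
    pft <- init$pft
    d <- init$d
    b <- agb_fast(d, pft, pv)
    stress <- numeric(length(d))
    patch <- with_stream(streams, "recruitment",
                         sample.int(n_patch, length(d), replace = TRUE))
  }
  deadwood <- 0; soil <- 0

  tot_cols <- c("year", "agb", "agb10", "basal_area", "stems", "stems_all",
                "gpp", "ra", "npp", "mortality_flux", "litter_flux", "rh",
                "nee", "seed_influx", "living_c", "deadwood_c", "soil_c",
                "total_c", "lai0", "lai05", "lai2", "recruits", "deaths")
  TOT <- matrix(0, years, length(tot_cols),
                dimnames = list(NULL, tot_cols))
  AGB <- matrix(0, years, n_pft)    # all trees, t_odm/ha
  AGB10 <- matrix(0, years, n_pft)  # dbh > 10 cm
  BA10 <- matrix(0, years, n_pft)
  ST10 <- matrix(0, years, n_pft)
  SDM <- matrix(0, years, length(bin_lower))
  LPM <- matrix(0, years, length(lai_heights))  # mean LAI profile
  LPLO <- matrix(0, years, length(lai_heights))
  LPHI <- matrix(0, years, length(lai_heights))

  for (t in seq_len(years)) {
    n <- length(d)
    mort_odm <- 0; litter_odm <- 0; gpp_sum <- 0; npp_sum <- 0
    deaths <- 0L

    if (n > 0) {
      h <- d / (1 / pv$h0[pft] + d / pv$h1[pft])
      ca <- pmin((pi / 4) * (pv$crown_d_ratio[pft] * d)^2, patch_area)
      la <- ca * pv$lai_tree[pft]
      cb <- h * (1 - pv$crown_frac[pft])
      L <- incident_light_all(patch, h, cb, la, n_patch, patch_area, config)

      # growth: individual carbon balance
      gpp <- gpp_fast(ca, pft, L$light, pv, config)
      npp <- (1 - pv$r_g[pft]) * (gpp - pv$r_m[pft] * b)
      npp <- pmax(npp, -b)  # cannot respire more biomass than exists
      g <- pmax(1 - (d / pv$d_max[pft])^config$gamma, 0)
      pos <- npp >= 0
      litter_i <- ifelse(pos, npp * (1 - g), 0)
      b <- b + ifelse(pos, npp * g, npp)
      b_allom <- agb_fast(d, pft, pv)
      grow <- which(b > b_allom * (1 + 1e-12))
      if (length(grow) > 0) {
        d[grow] <- diameter_from_agb_fast(b[grow], pft[grow], pv,
                                          d_start = d[grow], tol = 1e-12)
        b_allom[grow] <- agb_fast(d[grow], pft[grow], pv)
        over <- b[grow] > b_allom[grow]  # capped at d_max: excess to litter
        if (any(over)) {
          i <- grow[over]
          litter_i[i] <- litter_i[i] + (b[i] - b_allom[i])
          b[i] <- b_allom[i]
        }
      }
      stress <- pmax(0, 1 - b / pmax(b_allom, 1e-300))
      gpp_sum <- sum(gpp)
      npp_sum <- sum(npp)
      litter_odm <- sum(litter_i)

      # mortality: background + size + stress, then tree falls, then crowding
      rate <- pv$m_base[pft] + pv$ms0[pft] * exp(-pv$ms1[pft] * d) +
        pv$m_stress[pft] * stress + pv$msen[pft] * (d / pv$d_max[pft])^8
      u <- with_stream(streams, "mortality", stats::runif(2 * n))
      dead <- u[1:n] < 1 - exp(-rate)
      dead[b <= 1e-12] <- TRUE  # carbon starvation
      fallers <- which(dead & d >= pv$d_fall[pft] &
                         u[(n + 1):(2 * n)] < pv$p_fall[pft])
      if (length(fallers) > 0) {
        dead <- with_stream(streams, "fall",
                            fell_neighbours(fallers, dead, patch, ca, nb,
                                            patch_area))
      }
      keep <- !dead
      crowd <- crowding_thin(d, ca, h, cb, patch, keep, n_patch, patch_area,
                             config)
      keep <- keep & !crowd
      deaths <- sum(!keep)
      mort_odm <- sum(b[!keep])
      pft <- pft[keep]; d <- d[keep]; b <- b[keep]
      stress <- stress[keep]; patch <- patch[keep]
      floor_l <- L$floor_light
    } else {
      floor_l <- rep(1, n_patch)
      L <- NULL
    }

    # recruitment
    rec <- with_stream(streams, "recruitment", {
      counts <- stats::rpois(n_pft, pv$n_seed * area)
      total <- sum(counts)
      if (total > 0) {
        rp <- rep.int(seq_len(n_pft), counts)
        rpatch <- sample.int(n_patch, total, replace = TRUE)
        ok <- floor_l[rpatch] >= pv$i_seed[rp]
        list(pft = rp[ok], patch = rpatch[ok])
      } else {
        list(pft = integer(0), patch = integer(0))
      }
    })
    n_rec <- length(rec$pft)
    seed_odm <- 0
    if (n_rec > 0) {
      pft <- c(pft, rec$pft)
      d_new <- rep(0.01, n_rec)
      b_new <- agb_fast(d_new, rec$pft, pv)
      seed_odm <- sum(b_new)  # external biomass entering with recruits
      d <- c(d, d_new)
      b <- c(b, b_new)
      stress <- c(stress, numeric(n_rec))
      patch <- c(patch, rec$patch)
    }

    # carbon pools (per-ha fluxes)
    mort_ha <- mort_odm / area
    litter_ha <- litter_odm / area
    ps <- pools_step(deadwood, soil, mort_ha, litter_ha, config)
    deadwood <- ps$deadwood; soil <- ps$soil
    gpp_c <- config$odm_to_c * gpp_sum / area
    npp_c <- config$odm_to_c * npp_sum / area
    ra_c <- gpp_c - npp_c
    nee <- npp_c - ps$rh

    # records
    big <- d > 0.10
    agb_p <- pft_sum(b, pft, n_pft) / area
    agb10_p <- pft_sum(b[big], pft[big], n_pft) / area
    ba10_p <- pft_sum((pi / 4) * d[big]^2, pft[big], n_pft) / area
    st10_p <- pft_sum(rep(1, sum(big)), pft[big], n_pft) / area
    AGB[t, ] <- agb_p; AGB10[t, ] <- agb10_p
    BA10[t, ] <- ba10_p; ST10[t, ] <- st10_p
    SDM[t, ] <- tabulate(pmin(floor(d[big] * 10), 15), 15) / area
    lai0 <- lai05 <- lai2 <- 0
    if (!is.null(L)) {
      lp <- vapply(lai_heights, L$lai_at, numeric(n_patch))
      if (is.null(dim(lp))) lp <- matrix(lp, nrow = 1)
      LPM[t, ] <- colMeans(lp)
      LPLO[t, ] <- apply(lp, 2, min)
      LPHI[t, ] <- apply(lp, 2, max)
      lai0 <- mean(L$lai_at(0))
      lai05 <- mean(L$lai_at(0.5))
      lai2 <- mean(L$lai_at(2))
    }
    living_c <- config$odm_to_c * sum(b) / area
    TOT[t, ] <- c(t, sum(agb_p), sum(agb10_p), sum(ba10_p), sum(st10_p),
                  length(d) / area, gpp_c, ra_c, npp_c,
                  config$odm_to_c * mort_ha, config$odm_to_c * litter_ha,
                  ps$rh, nee, config$odm_to_c * seed_odm / area,
                  living_c, deadwood, soil,
                  living_c + deadwood + soil,
                  lai0, lai05, lai2, n_rec, deaths)
  }

  totals <- tibble::as_tibble(as.data.frame(TOT))
  by_pft <- tibble::tibble(
    year = rep(seq_len(years), n_pft),
    pft = rep(seq_len(n_pft), each = years),
    agb = as.vector(AGB), agb10 = as.vector(AGB10),
    basal_area = as.vector(BA10), stems = as.vector(ST10))
  size_dist <- tibble::tibble(
    year = rep(seq_len(years), length(bin_lower)),
    dbh_lower_cm = rep(bin_lower, each = years),
    stems = as.vector(SDM))
  lai_profile <- tibble::tibble(
    year = rep(seq_len(years), length(lai_heights)),
    height_m = rep(lai_heights, each = years),
    lai_mean = as.vector(LPM), lai_min = as.vector(LPLO),
    lai_max = as.vector(LPHI))
  final_trees <- tibble::tibble(pft = pft, d = d, b = b, patch = patch,
                                stress = stress)
  list(totals = totals, by_pft = by_pft, size_dist = size_dist,
       lai_profile = lai_profile, final_trees = final_trees)
}

pft_sum <- function(x, pft, n_pft) {
  if (length(x) == 0) return(numeric(n_pft))
  out <- numeric(n_pft)
  s <- rowsum(x, pft)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

lai_interp <- function(profile, heights, z) {
  stats::approx(heights, profile, xout = z, rule = 2)$y
}

fell_neighbours <- function(fallers, dead, patch, ca, nb, patch_area) {
  for (i in fallers) {
    tp <- nb[patch[i], sample.int(4, 1)]
    victims <- which(patch == tp & !dead)
    if (length(victims) > 0) {
      hit <- victims[stats::runif(length(victims)) < ca[i] / patch_area]
      dead[hit] <- TRUE
    }
  }
  dead
}

# smallest-first per-layer crown-area thinning among surviving trees
crowding_thin <- function(d, ca, top, base, patch, alive, n_patch,
                          patch_area, config) {
  removed <- logical(length(d))
  dz <- config$dz
  n_lay <- ceiling(config$max_height / dz)
  limit <- patch_area * (config$crowding_limit %||% 1)
  idx_alive <- which(alive)
  if (length(idx_alive) == 0) return(removed)
  lay_top <- pmin(pmax(ceiling(top / dz), 1), n_lay)
  lay_base <- pmin(pmax(floor(base / dz) + 1, 1), lay_top)
  # quick per-patch screen on the densest layer
  for (p in seq_len(n_patch)) {
    in_p <- idx_alive[patch[idx_alive] == p]
    if (length(in_p) < 2) next
    cca <- numeric(n_lay)
    for (j in in_p) {
      cca[lay_base[j]:lay_top[j]] <- cca[lay_base[j]:lay_top[j]] + ca[j]
    }
    if (max(cca) <= limit) next
    live <- rep(TRUE, length(in_p))
    ord <- order(d[in_p])
    while (max(cca) > limit) {
      worst <- which.max(cca)
      cand <- which(live & lay_base[in_p] <= worst & lay_top[in_p] >= worst)
      if (length(cand) == 0) break
      v <- cand[which.min(d[in_p][cand])]
      live[v] <- FALSE
      j <- in_p[v]
      cca[lay_base[j]:lay_top[j]] <- cca[lay_base[j]:lay_top[j]] - ca[j]
    }
    removed[in_p[!live]] <- TRUE
  }
  removed
}

`%||%` <- function(a, b) if (is.null(a)) b else a
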