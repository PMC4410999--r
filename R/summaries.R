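#' Equilibrium summaries of a simulation
#'
#' Time means, annual min/max ranges and across-replicate dispersion of all
#' recorded stand variables over an equilibrium window (by default years
#' 300-1000, assuming the succession has reached the old-growth state).
#'
#' @param sim A `forest_simulation` tibble from [simulate_forest()].
#' @param window Length-2 year window (inclusive).
#' @return A tibble `variable, pft, mean, min, max, rep_sd` (`pft` is `NA`
#'   for stand totals; per-PFT rows cover `agb`, `agb10`, `basal_area`,
#'   `stems`).
#' @export
equilibrium_stats <- function(sim, window = c(300, 1000)) {
  stopifnot(length(window) == 2, window[1] <= window[2])
  if (!any(sim$year >= window[1] & sim$year <= window[2])) {
    stop("equilibrium window [", window[1], ", ", window[2],
         "] is outside the simulated years", call. = FALSE)
  }
  w <- dplyr::filter(sim, .data$year >= window[1], .data$year <= window[2])
  vars <- setdiff(names(w), c("replicate", "year"))
  tot <- tidyr::pivot_longer(w, dplyr::all_of(vars), names_to = "variable") |>
    dplyr::group_by(.data$variable)
  rep_means <- tidyr::pivot_longer(w, dplyr::all_of(vars),
                                   names_to = "variable") |>
    dplyr::group_by(.data$variable, .data$replicate) |>
    dplyr::summarise(m = mean(.data$value), .groups = "drop") |>
    dplyr::group_by(.data$variable) |>
    dplyr::summarise(rep_sd = stats::sd(.data$m), .groups = "drop")
  tot <- dplyr::summarise(tot, mean = mean(.data$value),
                          min = min(.data$value), max = max(.data$value),
                          .groups = "drop") |>
    dplyr::left_join(rep_means, by = "variable") |>
    dplyr::mutate(pft = NA_integer_, .after = "variable")

  bp <- attr(sim, "by_pft")
  out_pft <- NULL
  if (!is.null(bp)) {
    bw <- dplyr::filter(bp, .data$year >= window[1], .data$year <= window[2])
    out_pft <- tidyr::pivot_longer(
      bw, dplyr::all_of(c("agb", "agb10", "basal_area", "stems")),
      names_to = "variable") |>
      dplyr::group_by(.data$variable, .data$pft) |>
      dplyr::summarise(mean = mean(.data$value), min = min(.data$value),
                       max = max(.data$value), rep_sd = NA_real_,
                       .groups = "drop")
  }
  dplyr::bind_rows(tot, out_pft)
}

#' Compare simulated equilibrium state with field targets
#'
#' Signed relative differences (percent) between the simulated equilibrium
#' means (census threshold dbh > 10 cm) and the field inventory targets,
#' per PFT and in total, for aboveground biomass, basal area and stems.
#'
#' @param stats Output of [equilibrium_stats()].
#' @param targets A `field_targets` object from [field_statistics()].
#' @return A tibble `variable, pft, simulated, observed, diff_pct`.
#' @export
compare_to_field <- function(stats, targets) {
  sim_map <- c(agb10 = "agb", basal_area = "basal_area", stems = "stems")
  tot <- purrr::map_dfr(names(sim_map), function(v) {
    tibble::tibble(
      variable = sim_map[[v]], pft = NA_integer_,
      simulated = stats$mean[stats$variable == v & is.na(stats$pft)],
      observed = targets$total[[sim_map[[v]]]])
  })
  per <- purrr::map_dfr(names(sim_map), function(v) {
    s <- dplyr::filter(stats, .data$variable == v, !is.na(.data$pft))
    tibble::tibble(
      variable = sim_map[[v]], pft = s$pft, simulated = s$mean,
      observed = targets$by_pft[[sim_map[[v]]]][
        match(s$pft, targets$by_pft$pft)])
  })
  dplyr::bind_rows(tot, per) |>
    dplyr::mutate(diff_pct = 100 * (.data$simulated - .data$observed) /
                    ifelse(.data$observed == 0, NA, .data$observed))
}

#' Stem size distribution
#'
#' Counts per 10-cm DBH class (census threshold 10 cm), per hectare. For a
#' simulation the annual binned counts are averaged over an equilibrium
#' window (with min/max range); for a census table the bins are computed
#' directly.
#'
#' @param x A `forest_simulation` or a census data frame with `dbh_cm`.
#' @param ... Passed to methods.
#' @return A tibble `dbh_lower_cm, stems` (plus `stems_min`, `stems_max` for
#'   simulations).
#' @export
size_distribution <- function(x, ...) UseMethod("size_distribution")

#' @rdname size_distribution
#' @param window Equilibrium window, years.
#' @export
size_distribution.forest_simulation <- function(x, window = c(300, 1000),
                                                ...) {
  sd_tbl <- attr(x, "size_distribution")
  dplyr::filter(sd_tbl, .data$year >= window[1], .data$year <= window[2]) |>
    dplyr::group_by(.data$dbh_lower_cm) |>
    dplyr::summarise(stems_min = min(.data$stems),
                     stems_max = max(.data$stems),
                     stems = mean(.data$stems), .groups = "drop") |>
    dplyr::relocate("dbh_lower_cm", "stems")
}

#' @rdname size_distribution
#' @param plot_area_m2 Plot area for per-ha upscaling of a census.
#' @param bin_width_cm DBH bin width, cm.
#' @export
size_distribution.data.frame <- function(x, plot_area_m2 = 2500,
                                         bin_width_cm = 10, ...) {
  size_distribution_bins(x$dbh_cm, bin_width_cm,
                         scale = 1e4 / plot_area_m2) |>
    dplyr::select("dbh_lower_cm", "stems")
}

#' LAI by height with across-patch and temporal range
#'
#' Mean simulated leaf area index above given heights, with the min/max band
#' over patches and years of the window (the vertical LAI profile of the
#' stand).
#'
#' @param sim A `forest_simulation`.
#' @param window Equilibrium window, years.
#' @return A tibble `height_m, lai, lai_min, lai_max`.
#' @export
lai_summary <- function(sim, window = c(300, 1000)) {
  lp <- attr(sim, "lai_profile")
  dplyr::filter(lp, .data$year >= window[1], .data$year <= window[2]) |>
    dplyr::group_by(.data$height_m) |>
    dplyr::summarise(lai = mean(.data$lai_mean),
                     lai_min = min(.data$lai_min),
                     lai_max = max(.data$lai_max), .groups = "drop")
}

#' Per-patch LAI at given heights for a tree list
#'
#' Evaluates the cumulative leaf area index above each requested height for
#' every patch of a stand snapshot, with the across-patch mean and range.
#'
#' @param trees Tibble with `patch`, `crown_top`, `crown_base`, `leaf_area`.
#' @param heights Heights (m) at which to evaluate the LAI.
#' @param n_patch Number of patches in the stand.
#' @param patch_area Patch ground area, m^2.
#' @param config Global configuration.
#' @return A tibble `height_m, patch, lai` plus summary columns via
#'   attribute `summary` (`height_m, mean, min, max`).
#' @export
stand_lai_profile <- function(trees, heights = c(0, 0.5, 2),
                              n_patch = max(trees$patch), patch_area = 400,
                              config = forest_config()) {
  stopifnot(all(heights >= 0))
  if (nrow(trees) == 0) {
    per <- tidyr::expand_grid(height_m = heights, patch = seq_len(n_patch)) |>
      dplyr::mutate(lai = 0)
  } else {
    L <- incident_light_all(trees$patch, trees$crown_top, trees$crown_base,
                            trees$leaf_area, n_patch, patch_area, config)
    per <- purrr::map_dfr(heights, function(z) {
      tibble::tibble(height_m = z, patch = seq_len(n_patch),
                     lai = L$lai_at(z))
    })
  }
  summ <- dplyr::group_by(per, .data$height_m) |>
    dplyr::summarise(mean = mean(.data$lai), min = min(.data$lai),
                     max = max(.data$lai), .groups = "drop")
  structure(per, summary = summ)
}

#' @importFrom generics glance
#' @export
generics::glance

#' @export
glance.forest_simulation <- function(x, window = NULL, ...) {
  if (is.null(window)) window <- c(ceiling(0.3 * max(x$year)), max(x$year))
  es <- equilibrium_stats(x, window)
  tot <- es[is.na(es$pft), ]
  g <- tibble::as_tibble(as.list(stats::setNames(tot$mean, tot$variable)))
  dplyr::mutate(g, replicates = length(unique(x$replicate)),
                years = max(x$year), window_start = window[1],
                window_end = window[2])
}

#' @export
tidy.forest_simulation <- function(x, ...) {
  bp <- attr(x, "by_pft")
  tidyr::pivot_longer(bp, dplyr::all_of(c("agb", "agb10", "basal_area",
                                          "stems")),
                      names_to = "variable")
}

#' @export
print.forest_simulation <- function(x, ...) {
  cat("Individual-based forest gap simulation: ",
      length(unique(x$replicate)), " replicate(s) x ", max(c(x$year, 0)),
      " yr, ", attr(x, "area_ha"), " ha\n", sep = "")
  NextMethod()
}
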