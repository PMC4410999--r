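#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a simulated forest trajectory
#'
#' Time series of per-PFT aboveground biomass, basal area and stem numbers
#' (`what = "structure"`), carbon pools (`"pools"`), productivity fluxes
#' (`"fluxes"`) or net ecosystem exchange (`"nee"`).
#'
#' @param object A `forest_simulation`.
#' @param what One of `"structure"`, `"pools"`, `"fluxes"`, `"nee"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.forest_simulation <- function(object,
                                       what = c("structure", "pools",
                                                "fluxes", "nee"),
                                       ...) {
  what <- match.arg(what)
  if (what == "structure") {
    dat <- tidy(object)
    dat <- dat[dat$variable %in% c("agb10", "basal_area", "stems"), ]
    p <- ggplot2::ggplot(dat, ggplot2::aes(.data$year, .data$value,
                                           colour = factor(.data$pft))) +
      ggplot2::geom_line(ggplot2::aes(group = interaction(.data$pft,
                                                          .data$replicate)),
                         alpha = 0.7) +
      ggplot2::facet_wrap(~variable, scales = "free_y") +
      ggplot2::labs(x = "year", y = NULL, colour = "PFT")
  } else if (what == "pools") {
    dat <- tidyr::pivot_longer(object,
                               dplyr::all_of(c("living_c", "deadwood_c",
                                               "soil_c")),
                               names_to = "pool")
    p <- ggplot2::ggplot(dat, ggplot2::aes(.data$year, .data$value,
                                           colour = .data$pool)) +
      ggplot2::geom_line(ggplot2::aes(group = interaction(.data$pool,
                                                          .data$replicate)),
                         alpha = 0.7) +
      ggplot2::labs(x = "year", y = "carbon stock (t_c/ha)")
  } else if (what == "fluxes") {
    dat <- tidyr::pivot_longer(object,
                               dplyr::all_of(c("gpp", "ra", "npp",
                                               "mortality_flux")),
                               names_to = "flux")
    p <- ggplot2::ggplot(dat, ggplot2::aes(.data$year, .data$value,
                                           colour = .data$flux)) +
      ggplot2::geom_line(ggplot2::aes(group = interaction(.data$flux,
                                                          .data$replicate)),
                         alpha = 0.7) +
      ggplot2::labs(x = "year", y = "flux (t_c ha-1 yr-1)")
  } else {
    p <- ggplot2::ggplot(object, ggplot2::aes(.data$year, .data$nee,
                                              group = .data$replicate)) +
      ggplot2::geom_line(alpha = 0.7) +
      ggplot2::geom_hline(yintercept = 0, linetype = 2) +
      ggplot2::labs(x = "year", y = "NEE (t_c ha-1 yr-1)")
  }
  p + ggplot2::theme_minimal()
}

#' @rdname autoplot.forest_simulation
#' @export
autoplot.forest_calibration <- function(object, ...) {
  free_cols <- setdiff(names(object$ledger), c("eval", "mse"))
  dat <- tidyr::pivot_longer(object$ledger, dplyr::all_of(free_cols),
                             names_to = "parameter")
  ggplot2::ggplot(dat, ggplot2::aes(.data$value, .data$mse)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::facet_wrap(~parameter, scales = "free_x") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "parameter value", y = "MSE") +
    ggplot2::theme_minimal()
}

#' Plot the simulated vs observed stem size distribution
#'
#' @param sim A `forest_simulation`.
#' @param census Optional census table for the observed distribution.
#' @param window Equilibrium window.
#' @param plot_area_m2 Census plot area, m^2.
#' @return A ggplot object.
#' @export
plot_size_distribution <- function(sim, census = NULL,
                                   window = c(300, 1000),
                                   plot_area_m2 = 2500) {
  sd_sim <- size_distribution(sim, window)
  p <- ggplot2::ggplot(sd_sim, ggplot2::aes(.data$dbh_lower_cm + 5,
                                            .data$stems)) +
    ggplot2::geom_col(fill = "firebrick", alpha = 0.6, width = 8) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$stems_min,
                                        ymax = .data$stems_max),
                           width = 2, colour = "firebrick") +
    ggplot2::labs(x = "DBH class (cm)", y = "stems per ha") +
    ggplot2::theme_minimal()
  if (!is.null(census)) {
    sd_obs <- size_distribution(census, plot_area_m2 = plot_area_m2)
    p <- p + ggplot2::geom_line(data = sd_obs, colour = "steelblue") +
      ggplot2::geom_point(data = sd_obs, colour = "steelblue")
  }
  p
}

#' Plot the vertical LAI profile with its simulated range
#'
#' @param sim A `forest_simulation`.
#' @param window Equilibrium window.
#' @param observed Optional tibble `height_m, lai` of field measurements.
#' @return A ggplot object.
#' @export
plot_lai_profile <- function(sim, window = c(300, 1000), observed = NULL) {
  ls <- lai_summary(sim, window)
  p <- ggplot2::ggplot(ls, ggplot2::aes(.data$lai, .data$height_m)) +
    ggplot2::geom_ribbon(ggplot2::aes(xmin = .data$lai_min,
                                      xmax = .data$lai_max),
                         fill = "darkgreen", alpha = 0.2) +
    ggplot2::geom_path(colour = "darkgreen") +
    ggplot2::labs(x = "LAI above height", y = "height (m)") +
    ggplot2::theme_minimal()
  if (!is.null(observed)) {
    p <- p + ggplot2::geom_point(data = observed, colour = "red")
  }
  p
}
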