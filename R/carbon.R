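#' Annual update of the deadwood and soil carbon pools
#'
#' Three-pool ecosystem carbon accounting: carbon leaves the living pool as
#' mortality and litter (organic dry matter converted to carbon by
#' `odm_to_c`), enters the deadwood pool, and from there is either respired
#' (`resp_deadwood`) or transferred to the upper-soil pool (`t_s`), which
#' respires at `resp_soil`. All transfers are first-order in the donor pool;
#' annual outflow rates are clipped so a pool can never go negative.
#'
#' @param deadwood,soil Pool sizes, t_c/ha.
#' @param mortality_odm Biomass lost to mortality this year, t_odm/ha.
#' @param litter_odm Litter (non-structural turnover), t_odm/ha.
#' @param config Global configuration (rates `t_s`, `resp_deadwood`,
#'   `resp_soil`, and `odm_to_c`).
#' @return A tibble with the updated pools and the year's heterotrophic
#'   fluxes: `deadwood, soil, deadwood_resp, soil_resp, deadwood_to_soil,
#'   rh` (all t_c/ha or t_c ha^-1 yr^-1).
#' @export
pools_step <- function(deadwood, soil, mortality_odm, litter_odm,
                       config = forest_config()) {
  stopifnot(all(mortality_odm >= 0), all(litter_odm >= 0),
            all(deadwood >= 0), all(soil >= 0))
  influx <- config$odm_to_c * (mortality_odm + litter_odm)
  out_rate <- config$t_s + config$resp_deadwood
  scale <- if (out_rate > 1) 1 / out_rate else 1  # outflow cannot exceed pool
  dw_to_soil <- config$t_s * scale * deadwood
  dw_resp <- config$resp_deadwood * scale * deadwood
  s_resp <- min(config$resp_soil, 1) * soil
  tibble::tibble(
    deadwood = deadwood + influx - dw_to_soil - dw_resp,
    soil = soil + dw_to_soil - s_resp,
    deadwood_resp = dw_resp,
    soil_resp = s_resp,
    deadwood_to_soil = dw_to_soil,
    rh = dw_resp + s_resp
  )
}

#' Net ecosystem exchange from annual fluxes
#'
#' \eqn{\mathrm{NEE} = \mathrm{NPP} - R_h = \mathrm{GPP} - R_a - R_h};
#' positive values mean the forest is a carbon sink, negative a source.
#'
#' @param fluxes A data frame with columns `gpp`, `ra` (autotrophic
#'   respiration) and `rh` (heterotrophic respiration), t_c ha^-1 yr^-1.
#' @return NEE, t_c ha^-1 yr^-1 (vectorised over rows).
#' @export
compute_nee <- function(fluxes) {
  stopifnot(all(c("gpp", "ra", "rh") %in% names(fluxes)))
  fluxes$gpp - fluxes$ra - fluxes$rh
}

#' Carbon stock report
#'
#' @param living,deadwood,soil Pool sizes, t_c/ha.
#' @return A tibble with the three pools and their exact total.
#' @export
carbon_report <- function(living, deadwood, soil) {
  tibble::tibble(living = living, deadwood = deadwood, soil = soil,
                 total = living + deadwood + soil)
}
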