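#' Annual gross production of a tree crown
#'
#' Leaf-level gross photosynthesis follows the saturating light response
#' \deqn{p(I) = \frac{p_{max}\,\alpha I}{p_{max} + \alpha I}}
#' (umol CO2 m^-2 leaf s^-1). Within the crown, light declines by
#' Lambert-Beer self-shading through the tree's own leaf layers
#' (\eqn{I(l) = I\,e^{-k l}}, `l` cumulative leaf area from the crown top,
#' 0..L with L = `lai_tree`), which integrates in closed form:
#' \deqn{P = A_c \frac{p_{max}}{k}
#'   \ln\!\frac{p_{max} + \alpha I}{p_{max} + \alpha I e^{-kL}}}
#' with \eqn{A_c} the crown projection area. The annual total converts to
#' organic dry matter through the configuration constant `c_odm` (active
#' photoperiod and CO2-to-odm stoichiometry).
#'
#' @param crown_area Crown projection area, m^2 (vectorised).
#' @param pft PFT id (recycled).
#' @param incident_light Fraction of above-canopy light at the crown top,
#'   in \[0, 1\].
#' @param params PFT parameter table.
#' @param config Global configuration (`i0`, `k`, `c_odm`).
#' @return Gross production, t_odm yr^-1 per tree.
#' @export
tree_gross_production <- function(crown_area, pft, incident_light,
                                  params = pft_parameters(),
                                  config = forest_config()) {
  stopifnot(all(incident_light >= 0), all(incident_light <= 1))
  pv <- param_vectors(params)
  check_pft(pft, pv)
  pft <- rep_len(pft, length(crown_area))
  gpp_fast(crown_area, pft, incident_light, pv, config)
}

gpp_fast <- function(crown_area, pft, incident_light, pv, config) {
  ai <- pv$alpha[pft] * config$i0 * incident_light
  pm <- pv$pmax[pft]
  L <- pv$lai_tree[pft]
  rate <- (pm / config$k) *
    log((pm + ai) / (pm + ai * exp(-config$k * L)))  # umol m^-2 crown s^-1
  crown_area * rate * config$c_odm
}

#' Annual biomass increment from the tree carbon balance
#'
#' Net assimilate after maintenance and growth respiration,
#' \eqn{\mathrm{NPP} = (1 - r_g)(\mathrm{GPP} - r_m B)}, allocated to stem
#' growth through the size limiter \eqn{g(d) = 1 - (d/d_{max})^\gamma}: as a
#' tree approaches its maximum diameter an increasing share of its
#' production turns over as litter instead of structural growth. Shaded
#' trees with GPP below maintenance have a negative balance and shrink.
#'
#' @param b Aboveground biomass, t_odm (vectorised).
#' @param d Stem diameter, m.
#' @param pft PFT id (recycled).
#' @param gpp Annual gross production, t_odm/yr (e.g.
#'   [tree_gross_production()]).
#' @param params PFT parameter table.
#' @param config Global configuration (growth limiter exponent `gamma`).
#' @return A tibble `npp` (net production), `increment` (biomass growth,
#'   t_odm/yr; negative when the balance is negative) and `litter`
#'   (non-structural turnover, t_odm/yr; zero for a negative balance).
#' @export
biomass_increment <- function(b, d, pft, gpp, params = pft_parameters(),
                              config = forest_config()) {
  stopifnot(all(gpp >= 0), all(b >= 0), all(d >= 0))
  pv <- param_vectors(params)
  check_pft(pft, pv)
  pft <- rep_len(pft, length(b))
  npp <- (1 - pv$r_g[pft]) * (gpp - pv$r_m[pft] * b)
  g <- pmax(1 - (d / pv$d_max[pft])^config$gamma, 0)
  inc <- ifelse(npp >= 0, npp * g, npp)
  litter <- ifelse(npp >= 0, npp * (1 - g), 0)
  tibble::tibble(npp = npp, increment = inc, litter = litter)
}

#' Update tree geometry to match a new biomass
#'
#' Inverts the biomass allometry (see [diameter_from_agb()]) and re-derives
#' height and crown geometry, keeping the individual's state internally
#' consistent after a growth step.
#'
#' @param d Current stem diameter, m (used as the root-finding start).
#' @param pft PFT id.
#' @param new_b Target biomass, t_odm.
#' @param params PFT parameter table.
#' @param patch_area Crown-area cap, m^2.
#' @return A tibble as [tree_geometry()], with the solved diameters.
#' @export
update_geometry <- function(d, pft, new_b, params = pft_parameters(),
                            patch_area = 400) {
  d_new <- diameter_from_agb(new_b, pft, params, d_start = d)
  tree_geometry(d_new, pft, params, patch_area = patch_area)
}
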