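#' Plant functional type parameter table
#'
#' Returns the per-PFT parameter set of the gap model: height-diameter
#' allometry, stem geometry, crown geometry, leaf photosynthesis, respiration,
#' mortality, tree-fall and recruitment parameters. The default table is the
#' calibrated parameter set for a lower montane old-growth forest at
#' Mt. Kilimanjaro with six PFTs spanning three maximum-height classes
#' (<16 m, 16-33 m, >33 m) and three shade-tolerance classes.
#'
#' Columns (units):
#' \describe{
#'   \item{pft}{integer id, 1..n}
#'   \item{height_class, light_class}{the trait classes defining the PFT}
#'   \item{h0, h1}{height allometry \eqn{h = d / (1/h_0 + d/h_1)}; h0 is the
#'     initial slope (m height per m diameter), h1 the asymptotic height (m)}
#'   \item{form_factor}{stem form factor (dimensionless)}
#'   \item{rho}{wood density, t organic dry matter (odm) per m^3}
#'   \item{d_max}{maximum stem diameter, m}
#'   \item{crown_d_ratio}{crown diameter per stem diameter (dimensionless)}
#'   \item{crown_frac}{crown depth as a fraction of tree height}
#'   \item{lai_tree}{leaf area per crown projection area, m^2/m^2}
#'   \item{pmax}{maximum leaf gross photosynthetic rate, umol CO2 m^-2 s^-1}
#'   \item{alpha}{initial slope of the leaf light response,
#'     umol CO2 per umol photons}
#'   \item{r_m}{maintenance respiration rate, yr^-1 (per unit biomass)}
#'   \item{r_g}{growth respiration fraction of assimilate (0..1)}
#'   \item{m_base}{background mortality rate, yr^-1}
#'   \item{ms0, ms1}{size-dependent mortality \eqn{m_s = ms0\,e^{-ms1 d}}
#'     (elevated mortality of small stems)}
#'   \item{msen}{senescence mortality coefficient: adds
#'     \eqn{msen\,(d/d_{max})^8}, so mortality rises steeply as a tree
#'     approaches its maximum diameter}
#'   \item{m_stress}{mortality rate per unit relative carbon deficit, yr^-1}
#'   \item{d_fall}{minimum diameter for a dying tree to fell neighbours, m}
#'   \item{p_fall}{probability that a dying tree above d_fall falls}
#'   \item{n_seed}{recruits reaching 1 cm dbh, ha^-1 yr^-1}
#'   \item{i_seed}{minimum relative light at the forest floor for
#'     establishment (fraction of above-canopy light)}
#' }
#'
#' @return A tibble with one row per PFT, class `pft_parameters`.
#' @export
#' @examples
#' pft_parameters()
pft_parameters <- function() {
  p <- tibble::tibble(
    pft           = 1:6,
    height_class  = c(">33", "16-33", "16-33", "16-33", "<16", "<16"),
    light_class   = c("tolerant", "tolerant", "intermediate", "intolerant",
                      "tolerant", "intolerant"),
    h0            = c(160, 120, 120, 130, 80, 90),
    h1            = c(50, 28, 28, 28, 14, 14),
    form_factor   = c(0.52, 0.50, 0.50, 0.45, 0.50, 0.40),
    rho           = c(0.60, 0.55, 0.50, 0.40, 0.55, 0.30),
    d_max         = c(1.70, 0.66, 0.76, 0.66, 0.38, 0.28),
    crown_d_ratio = c(20, 20, 20, 20, 20, 20),
    crown_frac    = c(0.35, 0.35, 0.35, 0.35, 0.35, 0.35),
    pmax          = c(5.14, 3.23, 4.07, 6.49, 3.23, 6.50),
    alpha         = c(0.05, 0.05, 0.05, 0.05, 0.05, 0.05),
    lai_tree      = c(3.30, 3.30, 3.30, 3.0, 3.30, 2.4),
    r_m           = c(0.0932, 0.0932, 0.0932, 0.0932, 0.0932, 0.0932),
    r_g           = c(0.25, 0.25, 0.25, 0.25, 0.25, 0.25),
    m_base        = c(0.005, 0.025, 0.026, 0.070, 0.045, 0.080),
    ms0           = c(0.06, 0.06, 0.06, 0.06, 0.06, 0.06),
    ms1           = c(25, 25, 25, 25, 25, 25),
    m_stress      = c(0.3, 0.3, 0.3, 0.3, 0.3, 0.3),
    msen          = c(0.035, 0.050, 0.050, 0.050, 0.050, 0.050),
    d_fall        = c(0.30, 0.30, 0.30, 0.30, 0.30, 0.30),
    p_fall        = c(0.30, 0.30, 0.30, 0.30, 0.30, 0.30),
    n_seed        = c(8, 41, 8, 10, 14, 12),
    i_seed        = c(0.010, 0.010, 0.040, 0.100, 0.010, 0.120)
  )
  class(p) <- c("pft_parameters", class(p))
  p
}

#' Global model configuration
#'
#' Stand-level constants shared across PFTs: the light model, the
#' photosynthesis unit conversion, the carbon-pool turnover rates and the
#' simulation grid geometry.
#'
#' @param k Canopy light extinction coefficient (Lambert-Beer), dimensionless.
#' @param dz Vertical discretization of the leaf-area profile, m.
#' @param i0 Mean photosynthetically active radiation above the canopy during
#'   the active period, umol photons m^-2 s^-1.
#' @param c_odm Conversion from a leaf gross photosynthetic rate of
#'   1 umol CO2 m^-2 s^-1 sustained over the photosynthetically active period
#'   of one year to organic dry matter, t_odm m^-2 yr^-1. The default folds a
#'   12-h photoperiod and CO2-to-odm stoichiometry into one named constant.
#' @param gamma Exponent of the growth limiter \eqn{g(d) = 1 - (d/d_{max})^\gamma}.
#' @param crowding_limit Maximum summed crown projection area per patch area
#'   allowed in any height layer before crowding mortality thins the layer
#'   (1 = strict crown packing; larger values allow crown overlap).
#' @param odm_to_c Carbon fraction of organic dry matter (t_c per t_odm).
#' @param t_s Deadwood-to-soil transfer rate, yr^-1.
#' @param resp_deadwood Deadwood respiration (decomposition to CO2) rate, yr^-1.
#' @param resp_soil Soil organic carbon respiration rate, yr^-1.
#' @param patch_size Patch edge length, m (gap-scale cell; 20 m).
#' @param max_height Top of the vertical profile, m.
#'
#' @return A named list, class `forest_config`.
#' @export
forest_config <- function(k = 0.7,
                          dz = 0.5,
                          i0 = 700,
                          c_odm = 4.0e-4,
                          gamma = 4,
                          crowding_limit = 1,
                          odm_to_c = 0.47,
                          t_s = 0.055,
                          resp_deadwood = 0.10,
                          resp_soil = 0.063,
                          patch_size = 20,
                          max_height = 55) {
  stopifnot(k > 0, dz > 0, i0 > 0, c_odm > 0,
            odm_to_c > 0, odm_to_c < 1,
            t_s >= 0, resp_deadwood >= 0, resp_soil >= 0, crowding_limit >= 1)
  structure(
    list(k = k, dz = dz, i0 = i0, c_odm = c_odm, gamma = gamma,
         crowding_limit = crowding_limit,
         odm_to_c = odm_to_c, t_s = t_s, resp_deadwood = resp_deadwood,
         resp_soil = resp_soil, patch_size = patch_size,
         max_height = max_height),
    class = "forest_config"
  )
}

#' Site configuration for the Kilimanjaro lower montane forest
#'
#' The calibrated global configuration used with [pft_parameters()] for the
#' FLM3-like stand: the carbon fraction implied by the site's biomass/carbon
#' pair (0.50) and pool turnover rates tuned to the old-growth equilibrium.
#'
#' @return A `forest_config` list.
#' @export
kilimanjaro_config <- function() {
  forest_config(odm_to_c = 0.50, gamma = 80, crowding_limit = 2.3,
                t_s = 0.055, resp_deadwood = 0.10, resp_soil = 0.063)
}

validate_pft_parameters <- function(params) {
  required <- c("pft", "h0", "h1", "form_factor", "rho", "d_max",
                "crown_d_ratio", "crown_frac", "lai_tree", "pmax", "alpha",
                "r_m", "r_g", "m_base", "ms0", "ms1", "m_stress", "msen", "d_fall",
                "p_fall", "n_seed", "i_seed")
  missing <- setdiff(required, names(params))
  if (length(missing) > 0) {
    stop("PFT parameter table is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(params$pft)) stop("duplicated pft ids", call. = FALSE)
  num <- params[setdiff(required, "pft")]
  if (any(vapply(num, function(x) any(!is.finite(x) | x < 0), logical(1)))) {
    stop("PFT parameters must be finite and non-negative", call. = FALSE)
  }
  if (any(params$r_g >= 1)) stop("r_g must be in [0, 1)", call. = FALSE)
  if (any(params$i_seed > 1)) stop("i_seed must be in [0, 1]", call. = FALSE)
  invisible(params)
}

#' Read and write a PFT parameter file
#'
#' The on-disk format is CSV or YAML with exactly the [pft_parameters()]
#' column names; the round trip is loss-free.
#'
#' @param path File path; format chosen by extension (`.csv`, `.yml`/`.yaml`).
#' @return `read_pft_parameters()` returns a validated `pft_parameters`
#'   tibble; `write_pft_parameters()` returns `path` invisibly.
#' @export
read_pft_parameters <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  p <- if (ext %in% c("yml", "yaml")) {
    tibble::as_tibble(lapply(
      as.data.frame(do.call(rbind, lapply(yaml::read_yaml(path), as.data.frame))),
      function(col) utils::type.convert(as.character(col), as.is = TRUE)))
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  validate_pft_parameters(p)
  class(p) <- c("pft_parameters", class(p))
  p
}

#' @rdname read_pft_parameters
#' @param params A `pft_parameters` tibble.
#' @export
write_pft_parameters <- function(params, path) {
  validate_pft_parameters(params)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    yaml::write_yaml(lapply(seq_len(nrow(params)),
                            function(i) as.list(params[i, ])), path)
  } else {
    readr::write_csv(params, path, progress = FALSE)
  }
  invisible(path)
}

# fast internal form: list of per-pft vectors indexed by position 1..max(pft)
param_vectors <- function(params) {
  validate_pft_parameters(params)
  ord <- order(params$pft)
  out <- lapply(params[ord, setdiff(names(params),
                                    c("height_class", "light_class"))],
                as.numeric)
  out$n_pft <- nrow(params)
  out
}
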