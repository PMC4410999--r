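#' Vertical leaf-area profile of a patch
#'
#' Spreads every tree's leaf area uniformly over the layers its crown spans
#' (discretization `dz`) and accumulates, per layer, the leaf area density
#' and the cumulative leaf area index (LAI) above the layer. Light follows
#' Lambert-Beer (Monsi-Saeki) extinction through the cumulative LAI, so the
#' relative irradiance is 1 at the canopy top and non-decreasing with height.
#'
#' @param trees A data frame with columns `crown_top`, `crown_base`,
#'   `leaf_area` (m^2 per tree), e.g. from [tree_geometry()].
#' @param patch_area Ground area of the patch, m^2.
#' @param config Global configuration, see [forest_config()].
#' @return A tibble `height_m` (layer lower edge), `lad` (leaf area per
#'   ground area in the layer), `cum_lai_above` (LAI at and above the layer's
#'   top... strictly above the layer), `rel_irradiance`.
#' @export
leaf_area_profile <- function(trees, patch_area = 400,
                              config = forest_config()) {
  dz <- config$dz
  n_lay <- ceiling(config$max_height / dz)
  lad <- layer_leaf_area(trees$crown_top, trees$crown_base, trees$leaf_area,
                         dz, n_lay) / patch_area
  cum_above <- rev(cumsum(rev(lad))) - lad  # LAI strictly above each layer
  tibble::tibble(
    height_m = (seq_len(n_lay) - 1) * dz,
    lad = lad,
    cum_lai_above = cum_above + lad,  # LAI above the layer's lower edge
    rel_irradiance = exp(-config$k * (cum_above + lad))
  )
}

# leaf area per layer (vector of length n_lay), uniform spread over the span
layer_leaf_area <- function(top, base, leaf_area, dz, n_lay) {
  out <- numeric(n_lay)
  if (length(top) == 0) return(out)
  lay_top <- pmin(pmax(ceiling(top / dz), 1), n_lay)
  lay_base <- pmin(pmax(floor(base / dz) + 1, 1), lay_top)
  span <- lay_top - lay_base + 1
  idx <- sequence(span) + rep(lay_base - 1L, span)
  vals <- rep(leaf_area / span, span)
  acc <- rowsum(vals, idx)
  out[as.integer(rownames(acc))] <- acc[, 1]
  out
}

#' Relative irradiance at a height in a patch profile
#'
#' Lambert-Beer extinction: \eqn{I(z)/I_0 = \exp(-k\,\mathrm{LAI}_{>z})},
#' evaluated on the discretized cumulative profile.
#'
#' @param profile A profile tibble from [leaf_area_profile()].
#' @param z Heights, m (vectorised, >= 0).
#' @param k Extinction coefficient.
#' @return Fraction of above-canopy light in (0, 1].
#' @export
irradiance_at <- function(profile, z, k = forest_config()$k) {
  if (any(z < 0)) stop("negative height", call. = FALSE)
  stopifnot(k >= 0)
  dz <- profile$height_m[2] - profile$height_m[1]
  lay <- pmin(pmax(floor(z / dz) + 1, 1), nrow(profile))
  exp(-k * profile$cum_lai_above[lay])
}

#' Light incident on a tree's crown top
#'
#' Irradiance at the tree's crown top computed from the leaf area of the
#' other trees only: the focal tree's own leaves are excluded from the
#' overshading sum (self-shading is handled analytically inside the crown
#' photosynthesis integral).
#'
#' @param tree Row index of the focal tree in `trees`.
#' @param trees All trees of the patch (including the focal tree).
#' @param patch_area Patch ground area, m^2.
#' @param config Global configuration.
#' @return Fraction of above-canopy light in (0, 1].
#' @export
tree_incident_light <- function(tree, trees, patch_area = 400,
                                config = forest_config()) {
  stopifnot(is.numeric(tree), tree >= 1, tree <= nrow(trees))
  profile <- leaf_area_profile(trees[-tree, , drop = FALSE], patch_area,
                               config)
  irradiance_at(profile, trees$crown_top[tree], config$k)
}

#' Relative light at the forest floor
#'
#' @inheritParams irradiance_at
#' @export
floor_light <- function(profile, k = forest_config()$k) {
  irradiance_at(profile, 0, k)
}

# engine-internal: incident light per tree for all patches at once.
# Trees are binned into (patch, layer) leaf-area fields; each tree sees the
# cumulative LAI of layers strictly above its own crown-top layer, which
# excludes its own leaves by construction.
incident_light_all <- function(patch, crown_top, crown_base, leaf_area,
                               n_patch, patch_area, config) {
  dz <- config$dz
  n_lay <- ceiling(config$max_height / dz)
  lay_top <- pmin(pmax(ceiling(crown_top / dz), 1), n_lay)
  lay_base <- pmin(pmax(floor(crown_base / dz) + 1, 1), lay_top)
  span <- lay_top - lay_base + 1
  idx <- sequence(span) + rep(lay_base - 1L, span)
  pat <- rep(patch, span)
  key <- (pat - 1L) * n_lay + idx
  acc <- rowsum(rep(leaf_area / span, span), key)
  lad <- matrix(0, n_lay, n_patch)
  lad[as.integer(rownames(acc))] <- acc[, 1]
  lad <- lad / patch_area
  # cum_above[l, p]: LAI strictly above layer l
  cum_above <- apply(lad, 2, function(x) rev(cumsum(rev(x))) - x)
  light <- exp(-config$k * cum_above[cbind(lay_top, patch)])
  floor_l <- exp(-config$k * colSums(lad))
  lai_at <- function(z) {
    lay <- pmin(max(floor(z / dz) + 1, 1), n_lay)
    cum_above[lay, ] + lad[lay, ]
  }
  list(light = light, floor_light = floor_l, lad = lad, lai_at = lai_at)
}
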