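#' Height-diameter allometry
#'
#' Saturating height curve \eqn{h(d) = d / (1/h_0 + d/h_1)}: initial slope
#' `h0` (m/m), asymptote `h1` (m). Monotone increasing in `d`, so tree height
#' never exceeds the PFT's height-class ceiling `h1`.
#'
#' @param d Stem diameter at breast height, m (vectorised).
#' @param pft PFT id (vectorised, recycled against `d`).
#' @param params PFT parameter table, see [pft_parameters()].
#' @return Height in m.
#' @export
#' @examples
#' height_from_diameter(c(0.1, 0.5, 1.0), 1, pft_parameters())
height_from_diameter <- function(d, pft, params = pft_parameters()) {
  stopifnot(all(d >= 0))
  pv <- param_vectors(params)
  check_pft(pft, pv)
  d / (1 / pv$h0[pft] + d / pv$h1[pft])
}

#' Aboveground biomass of a single stem
#'
#' Cylindrical stem volume corrected by a form factor and converted to mass:
#' \deqn{B = \frac{\pi}{4} d^2\, h(d)\, f\, \rho}
#' with `f` the form factor and `rho` wood density (t_odm/m^3). When `height`
#' is supplied (field-measured heights) it replaces the allometric `h(d)`.
#'
#' @inheritParams height_from_diameter
#' @param height Optional measured height, m; `NA` entries fall back to the
#'   allometric height.
#' @return Biomass in t organic dry matter (t_odm).
#' @export
#' @examples
#' tree_agb(0.5, 1, pft_parameters())
tree_agb <- function(d, pft, params = pft_parameters(), height = NULL) {
  stopifnot(all(d >= 0))
  pv <- param_vectors(params)
  check_pft(pft, pv)
  h <- height_from_diameter(d, pft, params)
  if (!is.null(height)) {
    use <- !is.na(height)
    h[use] <- height[use]
  }
  (pi / 4) * d^2 * h * pv$form_factor[pft] * pv$rho[pft]
}

check_pft <- function(pft, pv) {
  if (any(is.na(pft)) || any(pft < 1 | pft > pv$n_pft | pft != round(pft))) {
    stop("unknown pft id(s): ",
         paste(unique(pft[is.na(pft) | pft < 1 | pft > pv$n_pft]),
               collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

# internal: biomass and its derivative wrt d, vectorised on d (pv form)
agb_fast <- function(d, pft, pv) {
  (pi / 4) * d^3 * pv$form_factor[pft] * pv$rho[pft] /
    (1 / pv$h0[pft] + d / pv$h1[pft])
}

dagb_dd <- function(d, pft, pv) {
  a <- 1 / pv$h0[pft]
  b <- 1 / pv$h1[pft]
  c0 <- (pi / 4) * pv$form_factor[pft] * pv$rho[pft]
  c0 * d^2 * (3 * a + 2 * b * d) / (a + b * d)^2
}

#' Invert the biomass allometry: diameter from target biomass
#'
#' Solves \eqn{B(d) = b} for `d` by safeguarded Newton iteration (the biomass
#' curve is smooth and strictly increasing). Used by the simulator to keep
#' stem diameter, height and crown geometry consistent with biomass after
#' every growth step.
#'
#' @param b Target aboveground biomass, t_odm (vectorised).
#' @param pft PFT id (recycled).
#' @param params PFT parameter table.
#' @param d_start Optional starting diameters for the iteration.
#' @param tol Convergence tolerance on diameter, m.
#' @return Diameter in m; biomass beyond `B(d_max)` returns `d_max`.
#' @export
diameter_from_agb <- function(b, pft, params = pft_parameters(),
                              d_start = NULL, tol = 1e-10) {
  stopifnot(all(b >= 0))
  pv <- param_vectors(params)
  check_pft(pft, pv)
  pft <- rep_len(pft, length(b))
  d <- diameter_from_agb_fast(b, pft, pv, d_start = d_start, tol = tol)
  d
}

diameter_from_agb_fast <- function(b, pft, pv, d_start = NULL, tol = 1e-10) {
  dmax <- pv$d_max[pft]
  bmax <- agb_fast(dmax, pft, pv)
  capped <- b >= bmax
  # initial guess: invert the small-d limit B ~ (pi/4) h0 f rho d^3
  d <- if (is.null(d_start)) {
    pmin((b / ((pi / 4) * pv$form_factor[pft] * pv$rho[pft] * pv$h0[pft]))^(1 / 3) * 1.2,
         dmax)
  } else {
    pmin(pmax(d_start, 0), dmax)
  }
  d[b <= 0] <- 0
  active <- !capped & b > 0
  for (iter in 1:60) {
    if (!any(active)) break
    da <- d[active]
    fa <- agb_fast(da, pft[active], pv) - b[active]
    ga <- dagb_dd(da, pft[active], pv)
    step <- fa / pmax(ga, 1e-12)
    dn <- da - step
    # safeguard into (0, d_max]
    bad <- !is.finite(dn) | dn <= 0 | dn > dmax[active]
    dn[bad] <- 0.5 * (da[bad] + ifelse(fa[bad] > 0, 0, dmax[active][bad]))
    d[active] <- dn
    conv <- abs(dn - da) < tol
    active[active] <- !conv
  }
  d[capped] <- dmax[capped]
  d
}

#' Consistent tree geometry from diameter
#'
#' Derives height, crown diameter/area/depth and per-tree leaf area from stem
#' diameter via the PFT allometries. Crown projection area is capped at the
#' patch area (a crown cannot exceed its gap-scale cell).
#'
#' @inheritParams height_from_diameter
#' @param patch_area Patch area in m^2 used as the crown-area cap.
#' @return A tibble with columns `d, h, crown_diameter, crown_area,
#'   crown_top, crown_base, leaf_area`.
#' @export
tree_geometry <- function(d, pft, params = pft_parameters(),
                          patch_area = 400) {
  pv <- param_vectors(params)
  check_pft(pft, pv)
  pft <- rep_len(pft, length(d))
  h <- d / (1 / pv$h0[pft] + d / pv$h1[pft])
  ca <- pmin((pi / 4) * (pv$crown_d_ratio[pft] * d)^2, patch_area)
  tibble::tibble(
    d = d, h = h,
    crown_diameter = pv$crown_d_ratio[pft] * d,
    crown_area = ca,
    crown_top = h,
    crown_base = h * (1 - pv$crown_frac[pft]),
    leaf_area = ca * pv$lai_tree[pft]
  )
}

#' Fit the height-diameter allometry to inventory data
#'
#' Least-squares fit of \eqn{h = d/(1/h_0 + d/h_1)} to measured
#' (diameter, height) pairs, as used to derive the allometry from a local
#' forest inventory.
#'
#' @param data A data frame with columns `dbh_m` (or `dbh_cm`) and `height_m`.
#' @return A tibble with columns `h0`, `h1` and the residual standard error.
#' @export
fit_height_allometry <- function(data) {
  d <- if ("dbh_m" %in% names(data)) data$dbh_m else data$dbh_cm / 100
  h <- data$height_m
  keep <- is.finite(d) & is.finite(h) & d > 0 & h > 0
  d <- d[keep]; h <- h[keep]
  if (length(d) < 3) stop("need at least 3 (d, h) pairs", call. = FALSE)
  # linearisation d/h = 1/h0 + d/h1 gives starting values
  lin <- stats::lm(I(d / h) ~ d)
  start <- list(h0 = 1 / max(stats::coef(lin)[1], 1e-6),
                h1 = 1 / max(stats::coef(lin)[2], 1e-6))
  fit <- stats::nls(h ~ d / (1 / h0 + d / h1), start = start,
                    control = stats::nls.control(warnOnly = TRUE))
  est <- stats::coef(fit)
  tibble::tibble(h0 = unname(est["h0"]), h1 = unname(est["h1"]),
                 sigma = stats::sigma(fit))
}
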