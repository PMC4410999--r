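# gapforest

An individual-based forest gap model in R for estimating the structure,
productivity and carbon balance of tropical montane forests from a single
stem census.

One-off forest inventories tell you what is standing, but not what the stand
produces, loses and stores over time. `gapforest` bridges that gap for an
old-growth lower montane forest at Mt. Kilimanjaro (93 stems with
DBH > 10 cm on a 50 m × 50 m plot, 16 species): it classifies species into
six plant functional types (PFTs) from maximum height and two shade-tolerance
traits, calibrates an individual-based simulator against the inventory's
biomass, and then reads off quantities no snapshot can measure — gross and
net primary production, the living/deadwood/soil carbon pools, and the net
ecosystem exchange (NEE) of the mature forest.

The package is aimed at forest ecologists and carbon-cycle modellers who
want a transparent, fully testable gap model in R, with tidyverse-style
data-frame interfaces throughout.

## The model in brief

Every tree on a grid of 20 m × 20 m patches is simulated annually:

* **Light** — per-patch vertical leaf-area profiles with Lambert–Beer
  extinction, I(z)/I₀ = exp(−k·LAI₍>z₎), k = 0.7.
* **Growth** — an individual carbon balance: crown gross photosynthesis
  P = A_c (p_max/k)·ln[(p_max + αI)/(p_max + αI e^(−kL))], then
  NPP = (1 − r_g)(GPP − r_m B), allocated to stem growth through a size
  limiter g(d) = 1 − (d/d_max)^γ; diameter, height and crown follow from
  biomass via h = d/(1/h₀ + d/h₁) and B = (π/4) d² h f ρ.
* **Mortality** — stochastic background, small-stem, senescence and
  carbon-stress terms; large dying trees fall onto neighbouring patches and
  create gaps; crown crowding thins overloaded canopy layers.
* **Recruitment** — light-gated establishment at 1 cm DBH from a constant
  seed pool, with PFT-specific floor-light thresholds.
* **Carbon accounting** — three pools (living, deadwood, upper soil) with
  first-order transfers; NEE = NPP − Rh, positive = sink. The annual mass
  balance closes to machine precision.

Growth and mortality parameters, unknowable from a single census, are found
by inverse parameterization: Latin-hypercube search minimising the mean
square error between simulated equilibrium biomass (total and per PFT) and
the inventory targets.

A synthetic-inventory module (`generate_census()`, `generate_traits()`)
reproduces the stand's published statistics — 93 stems / 0.25 ha, dominance
fractions 36/24/6/5 %, a decreasing power-law size distribution — so the
whole pipeline runs and is tested without the original data files.

## Worked example

```r
library(gapforest)
library(dplyr)

# Field side: synthetic inventory -> PFTs -> per-hectare targets
census  <- generate_census(seed = 1)
traits  <- generate_traits(seed = 1)
mapping <- assign_pft(traits)
targets <- field_statistics(census, mapping)
targets
#> Field inventory targets (per hectare; upscaling factor 4)
#> Total: AGB 371.5 t_odm/ha, basal area 39.6 m2/ha, 372 stems/ha
#> # A tibble: 6 x 4
#>     pft     agb basal_area stems
#>   <int>   <dbl>      <dbl> <dbl>
#> 1     1 333.        29.5     128
#> 2     2  28.4        6.69    148
#> 3     3   6.62       1.63     32
#> ...

# Simulation side: 10 replicate 1000-yr successions from bare ground
sim <- simulate_forest(pft_parameters(), kilimanjaro_config(),
                       years = 1000, area_ha = 1, replicates = 10, seed = 1)

glance(sim, window = c(300, 1000)) |>
  select(agb10, basal_area, stems, gpp, ra, npp, nee)
#>      agb10 basal_area    stems      gpp       ra      npp         nee
#> 1 354.4465   36.99149 256.9151 23.39989 18.30349 5.096403 0.008593401

glance(sim, window = c(300, 1000)) |>
  select(living_c, deadwood_c, soil_c, total_c, mortality_flux, lai0)
#>   living_c deadwood_c   soil_c total_c mortality_flux     lai0
#> 1 178.1665   32.82381 28.66563 239.656       4.283775 4.333493

compare_to_field(equilibrium_stats(sim, c(300, 1000)), targets) |>
  filter(is.na(pft))
#>     variable pft simulated observed diff_pct
#> 1        agb  NA       354    371.5    -4.59
#> 2 basal_area  NA        37     39.6    -6.51
#> 3      stems  NA       257    372.0   -30.94
```

Reading the output: over the old-growth window (years 300–1000) the
simulated stand carries ~354 t of dry biomass and ~37 m² basal area per
hectare, within ~5–7 % of the inventory, while stem numbers run ~31 % low —
the model loses suppressed 10–20 cm understory stems faster than the real
forest does, a known structural bias. The mature forest fixes ~23.4 t C
ha⁻¹ yr⁻¹ (GPP), respires ~18.3 of it autotrophically (NPP ≈ 5.1), loses
~4.3 to mortality, stores ~178 + 33 + 29 ≈ 240 t C/ha in the living,
deadwood and soil pools, and has a long-run NEE of ~0.01 t C ha⁻¹ yr⁻¹: an
old-growth stand that is carbon-neutral on average.

`autoplot(sim, "structure")`, `autoplot(sim, "pools")`, `autoplot(sim, "nee")`,
`plot_size_distribution(sim, census)` and `plot_lai_profile(sim)` draw the
standard diagnostics; `calibrate_forest()` exposes the inverse
parameterization (see `vignette("forest-carbon-model")` for the full model
description).

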