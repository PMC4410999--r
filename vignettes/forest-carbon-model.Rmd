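---
title: "An individual-based gap model for the carbon balance of a tropical montane forest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An individual-based gap model for the carbon balance of a tropical montane forest}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`gapforest` simulates a species-rich tropical montane forest tree by tree, on
a grid of 20 m x 20 m patches (the typical scale of a tree-fall gap), in
annual steps. Its purpose is to connect a single stem census of an old-growth
stand — here a lower montane forest on Mt. Kilimanjaro, 93 stems with
DBH > 10 cm on a 50 m x 50 m plot — to quantities that a one-off inventory
cannot deliver: gross and net primary production, the partitioning of
ecosystem carbon into living biomass, deadwood and soil, and the net
ecosystem exchange (NEE) of the mature stand.

This vignette documents the model itself: the process equations, the meaning
and provenance of every tunable parameter, the synthetic inventory generator,
the inverse parameterization, and the numerical and design choices a user
should know before trusting (or modifying) the results.

## Model structure

### Plant functional types

Tree species are grouped into six plant functional types (PFTs) by the cross
of maximum-height classes (<16 m, 16–33 m, >33 m) and shade-tolerance classes
(tolerant, intermediate, intolerant). Height classes come directly from a
species' maximum attainable height. Shade tolerance is scored from two leaf
and stem economics traits: species are ranked on
$z(\mathrm{SDMC}) - z(\mathrm{leaf\ N})$ — high stem dry matter content and
low leaf nitrogen indicate conservative, shade-tolerant life histories — and
the ranking is cut into terciles. An expert `light_class_override` column
always wins over the trait score; this matters because a rank-based tercile
rule forces fixed class proportions, which a six-species example table cannot
satisfy. Of the nine conceivable (height x light) cells only six occur at
this site; `assign_pft()` treats an unmatched cell as an error rather than
guessing. The boundary convention for height classes is half-open:
$[0,16)$, $[16,33)$, $[33,\infty)$, so a species of exactly 16 m falls in the
middle class.

### Geometry and allometry

Stem diameter $d$ (m) is the primary state variable of a tree; everything
else derives from it:

* height $h(d) = d / (1/h_0 + d/h_1)$, a saturating curve with initial slope
  $h_0$ and asymptote $h_1$ (the height-class ceiling);
* aboveground biomass $B(d) = \tfrac{\pi}{4} d^2\, h(d)\, f\, \rho$ with form
  factor $f$ and wood density $\rho$ (t organic dry matter, odm, per m^3);
* crown diameter $= c_d \cdot d$ (default $c_d = 20$), crown projection area
  capped at the patch area; crown depth a fixed fraction (0.35) of height;
* one-sided leaf area $=$ crown area $\times$ `lai_tree`.

`diameter_from_agb()` inverts $B(d)$ with a safeguarded Newton iteration
(tolerance $10^{-10}$ m) so the simulator can move biomass and keep geometry
consistent. For field-side biomass, measured heights replace $h(d)$ when the
census provides them; the simulator always uses the allometric height, so
that simulated and observed biomass rest on the same assumptions.

### Light climate

Within a patch, each tree's leaf area is spread uniformly over the 0.5-m
layers its crown spans. Light declines through the cumulative leaf area index
(LAI) by Lambert–Beer (Monsi–Saeki) extinction,
$I(z)/I_0 = e^{-k\,\mathrm{LAI}_{>z}}$, with a single PFT-independent
extinction coefficient $k = 0.7$. Crowns shade by layer only — no lateral
position within the patch, the standard gap-model simplification — and
patches do not shade each other. A tree's incident light is evaluated at its
crown top excluding its own leaves; self-shading is handled analytically
inside the crown production integral instead.

### Tree carbon balance

Leaf-level gross photosynthesis follows the saturating response
$p(I) = p_{max}\alpha I / (p_{max} + \alpha I)$. Integrated through the
tree's own leaf layers with extinction $k$ this gives the closed form

$$P = A_c\,\frac{p_{max}}{k}\,
  \ln\frac{p_{max} + \alpha I}{p_{max} + \alpha I e^{-kL}}$$

with $A_c$ the crown area and $L$ the tree's leaf area index. The annual
unit conversion is a single named constant `c_odm`
($4\times10^{-4}$ t odm m$^{-2}$ yr$^{-1}$ per µmol CO$_2$ m$^{-2}$ s$^{-1}$,
folding a 12-h photoperiod and CO$_2$-to-dry-mass stoichiometry), with
above-canopy radiation `i0` = 700 µmol m$^{-2}$ s$^{-1}$.

Net production per tree is
$\mathrm{NPP} = (1 - r_g)(\mathrm{GPP} - r_m B)$: maintenance respiration
proportional to biomass, growth respiration a fixed fraction of the surplus.
A positive balance is split by the size limiter
$g(d) = 1 - (d/d_{max})^{\gamma}$: a share $g$ becomes structural growth
(diameter increment via the inverse allometry), the rest turns over as
litter. A negative balance shrinks biomass but not diameter — wood is not
resorbed — and the relative deficit $1 - B/B_{allom}(d)$ is carried as a
stress level that feeds stress mortality. Positive growth refills the
deficit before new diameter growth, so for trees growing in good light
$B = B_{allom}(d)$ holds exactly after every step.

### Mortality, gaps and crowding

A tree dies in a year with probability $1 - e^{-m}$, where

$$m = m_{base} + ms_0\,e^{-ms_1 d} + msen\,(d/d_{max})^8 + m_{stress}\cdot s.$$

The four terms are background mortality, elevated mortality of small stems,
senescence of trees approaching their maximum diameter, and carbon-stress
mortality of suppressed trees (with $s$ the relative deficit). The
senescence term matters for the stand-level carbon budget: without it, large
trees park at $d_{max}$ and convert their whole production to litter, which
starves the mortality flux that in an old-growth stand should roughly equal
NPP.

A dying tree with $d \ge$ 0.30 m falls with probability `p_fall` = 0.3 onto
a uniformly chosen von-Neumann neighbour patch (torus edges) and kills each
tree there with probability equal to its crown area over the patch area —
the gap-creation mechanism that drives the model's characteristic biomass
fluctuations. Independently, crown-space competition thins a patch whenever
the summed crown projection area in any 0.5-m layer exceeds
`crowding_limit` × patch area, removing the smallest spanning trees first
and no more than needed. The site configuration uses `crowding_limit` = 2.3:
canopies of this stature overlap substantially, and a strict limit of 1
caps the emergent biomass far below what the inventory shows.

### Recruitment

Each PFT receives a Poisson number of candidate recruits per year
(`n_seed` ha$^{-1}$ yr$^{-1}$, entering at 1 cm DBH) on uniformly chosen
patches; a candidate establishes only where relative floor light is at
least `i_seed`. Shade-tolerant PFTs establish under almost closed canopy
(`i_seed` = 0.01); pioneers need a gap (0.10–0.12), which is why their share
collapses below 1 % of stems once the canopy closes. The recruitment pool is
constant — the single simulated hectare is treated as embedded in continuous
forest, without parent-tree seed limitation.

### Ecosystem carbon pools and NEE

Three pools are tracked in t carbon/ha: living vegetation
(`odm_to_c` × standing biomass), deadwood and upper soil. Mortality and
litter feed deadwood; deadwood decomposes to CO$_2$ (`resp_deadwood` = 0.10
yr$^{-1}$) or transfers to soil (`t_s` = 0.055 yr$^{-1}$); soil respires at
`resp_soil` = 0.063 yr$^{-1}$. All transfers are first order in the donor
pool, with rates clipped so a pool cannot go negative. Then

$$\mathrm{NEE} = \mathrm{NPP} - R_h
  = \mathrm{GPP} - R_a - R_{deadwood} - R_{soil},$$

positive when the forest is a carbon sink. The master mass-balance identity
— the annual change of (living + deadwood + soil) equals
GPP − $R_a$ − $R_h$ + seed influx — holds to machine precision every
simulated year and is asserted in the test suite. The seed-influx term is
the biomass that 1-cm recruits carry in from outside the stand
(≈ 0.004 t C ha$^{-1}$ yr$^{-1}$, three orders of magnitude below the other
fluxes); it is recorded explicitly rather than silently leaked so the ledger
closes exactly.

The carbon fraction `odm_to_c` defaults to 0.47 package-wide; the
Kilimanjaro site configuration uses 0.50, the value implied by the stand's
reported biomass–carbon pair (385 t odm/ha of living biomass alongside
193 t C/ha in living vegetation).

### Process order and random numbers

Within a year: light → growth → mortality (including falls and crowding) →
recruitment → carbon pools. The order is fixed so results are reproducible;
it follows gap-model convention (light is computed on the standing canopy at
the start of the year). Randomness is split into three independent streams
per replicate — mortality draws, fall targets/victims, recruitment — so
switching one process off does not shift another's draws, and a (seed,
configuration) pair reproduces a run bit for bit.

## Parameter values

`pft_parameters()` ships the calibrated six-PFT table for the Kilimanjaro
lower montane stand, and `kilimanjaro_config()` the matching global
constants. Allometric and geometric parameters are fixed from the
inventory's structure (heights, crown expansion, the stand's biomass-to-basal
area ratio); physiological rates ($p_{max}$, $\alpha$, $r_m$, $r_g$) sit in
the typical range for tropical trees with shade-tolerance ordering
(pioneers photosynthesize faster and respire faster); growth and mortality
parameters are outputs of the package's own inverse parameterization against
the stand's biomass (total and per PFT), as no repeated inventories exist to
measure them directly. They are starting points for this site, not
universal constants; any of them can be varied through the parameter table
or the calibration interface.

Two parameters deserve explicit caveats. `gamma` (site value 80) makes the
growth limiter effectively a hard stop near $d_{max}$; smaller values divert
a visible share of NPP into litter well before trees reach their maximum
size, which depresses the simulated mortality flux below what an old-growth
stand in equilibrium shows. `crowding_limit` (2.3) is the packing density of
crowns per canopy layer; the emergent equilibrium biomass responds strongly
to it, and it should be recalibrated before the model is applied to a stand
of different stature.

## The synthetic inventory

`generate_census()` and `generate_traits()` emulate the field side so the
entire pipeline — reading, classifying, calibrating, validating — runs
without access to the original data files. The generator reproduces the
stand's published statistical structure: 93 stems of 16 species on 0.25 ha,
the four dominants at 36 %, 24 %, 6 % and 5 % of stems (largest-remainder
rounding, every species present), the remaining 29 % spread over twelve
rarer species by a geometric series (ratio 0.75), and a decreasing stem-size
distribution from a truncated power law (exponent 1.3, lower truncation at
the 10-cm census threshold, species-specific upper bounds so the very large
diameters belong to the tall emergents).

Diameters are a systematic quantile sample of that law rather than an iid
draw: the real plot is one fixed inventory, not a resample, and a quantile
sample gives every synthetic census the stand's size structure while
heights (lognormal noise around the allometry, CV 8 %), positions and trait
values stay stochastic. Trait values are drawn from well-separated
class distributions (tolerant: SDMC ≈ 0.55 g/g, leaf N ≈ 18 mg/g;
intolerant: ≈ 0.35 and ≈ 30), so the tercile classifier recovers the
generating PFT for every species; the generating PFT is retained in a
`true_pft` column for exactly that test.

What the generator does *not* emulate: spatial clustering of stems,
phylogenetic trait correlation, measurement error in DBH, and any real
census's deviation from a smooth size law. Tests that pass on synthetic
censuses therefore demonstrate that the pipeline is correct and that the
model can reproduce a stand *with the published summary statistics* — not
that it would fit any particular real inventory row for row.

## Inverse parameterization

`calibrate_forest()` searches a box of free parameters — by default with a
Latin hypercube sample, alternatively uniform-random or a grid — and scores
each candidate by the weighted mean square error between simulated
equilibrium aboveground biomass (total and per PFT, census threshold
DBH > 10 cm) and the field targets. The objective is deterministic given its
seed, averages a configurable number of replicate runs (default 2) to damp
simulation noise, logs every evaluation in a ledger, and returns the argmin
with the full parameter table reassembled. Non-finite simulation output is
assigned a large penalty and logged, never silently dropped.

Because the stochastic objective has sampling noise of a few percent, the
argmin over a wide box tends to select flukes; the shipped workflow
therefore calibrates within moderately narrow boxes around the default
table (itself the product of longer exploratory calibration at larger
budgets). The acceptance script uses 40 Latin-hypercube evaluations of
400-yr, 1-ha runs with 2 replicates each — about seven minutes of computing —
followed by the full 10 × 1000-yr experiment; the test suite demonstrates
the same machinery at smaller sizes, including a parameter-recovery check
where targets generated by the model itself (with a known, deliberately
shifted mortality) are recovered to within sampling error.

## Simulation experiments and summaries

The standard experiment is succession from bare ground on 1 ha (25 patches)
over 1000 years with 10 replicate runs; the old-growth state is summarised
as the mean over years 300–1000, by which time the biomass trend is
statistically indistinguishable from zero (this is asserted, per replicate,
in the acceptance tests). `equilibrium_stats()` returns means, annual
min/max ranges and across-replicate dispersion for every recorded variable;
`compare_to_field()` reports signed percentage differences against the
inventory; `size_distribution()` and `lai_summary()` produce the 10-cm DBH
histogram and the vertical LAI profile with their simulated ranges.

Two known, deliberate discrepancies with the field data carry over from the
model's structure. Stem numbers are lower than the inventory (≈ 240 vs
≈ 350–372 per ha), with the deficit confined to the 10–20 cm class: the
simulated understory loses suppressed stems to carbon-stress mortality
faster than the real stand does. And the simulated LAI near the ground sits
below the field value of 6 because herbs and shrubs — real contributors to
floor-level leaf area — are not modelled; the profile is essentially flat
below the canopy, so the 0-m and 2-m values differ much less in the
simulation than in the field (≈ 4.4 against the field's 6 and 4).

The mortality flux deserves the same honesty: in equilibrium the model's
aboveground loss to mortality events is NPP minus litter turnover
(≈ 4.2–4.4 of an NPP near 5 t C ha$^{-1}$ yr$^{-1}$), at the lower edge of
a ±10 % band around the reported 4.7, because some production cycles
through litter rather than whole-tree death no matter how steep the growth
limiter is made.

## Numerical choices

* Vertical discretization Δz = 0.5 m; the top of the profile at 55 m clears
  the tallest emergents.
* The crown production integral is closed-form; the test suite checks it
  against a 10⁴-sub-layer quadrature at 10⁻⁶ relative tolerance.
* Allometry inversion: vectorised Newton with bisection safeguards,
  tolerance 10⁻¹⁰ m; round trips biomass → diameter → biomass at 10⁻⁸.
* Rates are converted to probabilities as $1 - e^{-\Sigma m}$, which keeps
  summed causes consistent.
* Degenerate inputs: empty patches yield a zero profile and full light;
  zero-biomass trees die of starvation in the same year; biomass above
  $B(d_{max})$ pins the diameter at $d_{max}$ and routes the excess to
  litter; an empty census yields all-zero field targets.
* Pool outflow rates are clipped so annual outflow never exceeds the pool.

## Limitations

The model has no water or nutrient limitation and no temperature response —
it simulates a climatically undisturbed stand, so climate-change or land-use
scenarios are outside its scope. Lateral light between patches, directional
sun angles, seed dispersal kernels and spatially explicit stem positions
within patches are not represented. The calibration targets only biomass;
structure variables (stems, basal area, size distribution, LAI) are
validation output, and their residual misfits are reported, not tuned away.
Parameter values are site-calibrated for one lower montane stand and should
be re-derived before use elsewhere.
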