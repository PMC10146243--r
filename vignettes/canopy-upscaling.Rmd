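---
title: "From leaf physiology to canopy fluxes: models and choices in canopyflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From leaf physiology to canopy fluxes: models and choices in canopyflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopyflux)
```

# The problem

How much of the difference in canopy carbon gain and water use between two
fruit-tree genotypes comes from *where their leaves are* (canopy structure)
and how much from *what their leaves do* (leaf function)? `canopyflux`
answers this by simulation: it reconstructs explicit 3D canopies, computes
the light climate of every part of the crown, runs a coupled
photosynthesis–stomatal-conductance model for every leaf class, integrates
to daily canopy totals, and then swaps structure and function between
genotypes in a factorial scenario design so their contributions can be
partitioned.

The package is organized as a pipeline of independently testable stages,
and every input it needs can be generated synthetically from known ground
truth, so the whole chain is verifiable by round-trip tests.

# Canopy reconstruction

Digitized shoot skeletons record only the 3D endpoints and type (long,
short, bourse) of each current-year shoot. Leaves are added by allometry:

- shoot leaf area `SLA = a·SL + b` and leaf number `SLN = a·SL + b` from
  shoot length `SL` (leaf number rounded to the nearest integer, floor 1;
  negative predictions clamped at 0);
- every leaf on a shoot carries the mean area `SLA/SLN`; its length comes
  from the quadratic leaf allometry `LA = a_LA · LL²`, and its width and
  petiole length from linear relations in `LL`;
- leaves are planar hexagons whose length, maximum width and area all match
  the allometric targets exactly (the hexagon's mid-section extent is the
  free parameter that absorbs the area constraint; midrib curvature and
  lamina folding are ignored, as their effect on light interception is
  weak);
- insertion points are evenly spaced at the mean internode length
  `SL/SLN`; azimuths advance 144° per node (2/5 phyllotaxy) from a random
  initial azimuth per shoot; elevation and rolling angles are drawn from
  per-shoot-type histograms (default bin width 10°, configurable, since
  field protocols rarely record how angle measurements were binned).

Coordinates are x = East, y = North, z = up, azimuth clockwise from North,
elevation above the horizontal. This must be stated somewhere because
nothing in the input formats fixes the axes; it is this package's
convention.

Leaf area index is total leaf area over the ground area allotted to one
tree (2.0 m × 3.5 m spacing by default).

# Radiation

The canopy becomes a regular voxel grid (default edge 0.3 m, which
resolves a 3 m crown into ten layers). Each voxel carries a leaf area
density and the actual per-leaf normals assigned to it, so the projection
coefficient G toward any direction is the area-weighted mean |n·u| of real
leaf orientations, not a fitted distribution.

A parallel beam is traced through the grid with an exact voxel-walking
algorithm; within a voxel the flux decays by `exp(−G · LAD · path)`, and
the decrement is deposited there. Interception plus transmission equals
the incident flux on the footprint *exactly* — scattering is neglected for
PPFD (leaf absorptance 0.85), which keeps the conservation oracle exact.
Rays can exit the sides freely (isolated tree, the default) or wrap
horizontally (laterally infinite canopy), which reproduces the textbook
`exp(−G·LAI/sin h)` slab transmittance to machine precision.

Diffuse light uses the canonical 46-direction "turtle" sky. Direction
weights are the fractions of horizontal diffuse irradiance under a uniform
overcast radiance, computed once by numerical integration over each
direction's spherical Voronoi cell; they sum to 1 exactly. Because
interception is linear in flux, the 46-direction geometry is precomputed
once per scene and reused at every timestep.

Measured total PPFD is split into direct and diffuse with an hourly
clearness-index model (fully diffuse at kt ≤ 0.22, clear-sky residual
fraction beyond the upper regime); the split always sums to the input.
NIR is derived from PAR energy (PAR taken as 48% of shortwave) and split
in exactly the same direct/diffuse ratio as PPFD. Atmospheric longwave
uses a Brutsaert clear-sky emissivity modulated by a cloud fraction
inferred from the clearness index. Solar position uses Spencer's
declination series under local solar time.

Site latitude is configurable everywhere and defaults to 34.5° N,
consistent with the orchard region the defaults emulate; the 806 m
altitude sets the default air pressure (92.1 kPa).

# Leaf gas exchange

Photosynthesis is the Farquhar–von Caemmerer–Berry model: the minimum of
the Rubisco-limited and RuBP-regeneration-limited rates minus dark
respiration, with electron transport from a non-rectangular hyperbola
(α = 0.24 on an absorbed basis, θ = 0.9). The temperature-response
constants (Kc, Ko, Γ*, activation energies) are the Bernacchi et al.
(2001) in-vivo set — published constant sets differ, so the package ships
one named, documented, swappable set and uses it identically in the
forward model and in all fits, which is what makes the 25 °C
back-transformation exactly self-consistent.

Stomatal conductance is the multiplicative Jarvis model
`g_s = g_smax · f(PPFD) · f(T) · f(VPD)`, each factor clipped to [0, 1]:

- `f(PPFD)`: saturating hyperbola with half-saturation K (simplest
  monotone form consistent with a conductance that keeps rising to the
  highest measured PPFD);
- `f(T)`: symmetric optimum curve `1 − ((T − T_opt)/breadth)²` — only
  optima are reported for the field data, so the minimal shape with an
  optimum and a breadth is used;
- `f(VPD)`: plateau at 1 up to a threshold VPD₀, then a linear decline —
  the empirically observed closure pattern, with the threshold a fitted
  parameter.

The two models are coupled through the diffusion identity
`A(C_i) = (g_s/1.6)(C_a − C_i)` (1.6 = water/CO₂ diffusivity ratio),
solved by bracketed bisection plus Newton polishing; the residual at the
returned root is below 10⁻⁶. The residual is strictly monotone in `C_i`,
so the solution is unique. At night the PPFD factor closes the stomata
entirely; that degenerate case bypasses the root solve (`A = −R_d`,
`E = 0`, `C_i` reported at `C_a` by convention). Transpiration is
`g_s · VPD_surf / P`. With the optional energy balance the leaf
temperature solves the budget (absorbed radiation = thermal emission +
sensible + latent, boundary-layer conductance ∝ √(wind/leaf size),
residual < 0.01 W m⁻²) and the surface VPD follows the leaf-to-air vapour
gradient; by default the leaf is at air temperature and `VPD_surf =
VPD_air`, because gas-exchange measurements of this kind report
leaf-surface conditions directly and carry no boundary-layer model.

## The nitrogen gradient

Within-canopy acclimation is two chained linear maps: leaf nitrogen per
area from daily cumulated PPFD, then V_cmax25, J_max25, R_d25 and g_smax
from nitrogen (R_d declining with N in these canopies). Each voxel's
PPFD_d is computed once, for a clear reference day at simulation start,
and held fixed: leaf nitrogen acclimates over weeks, slowly relative to
the simulated window, so re-deriving parameters per day would add noise
without fidelity.

# Inverse procedures

Every fit is the exact inverse of the corresponding generator at zero
noise, and that is tested:

- **A–Ci fitting**: nonlinear least squares on the forward model,
  parameterized on the log scale for positivity, multistart with best-RSS
  selection. R_d can be fixed (e.g. measured pre-dawn, the default when a
  value is supplied) or co-estimated. A regime screen warns when the curve
  never crosses the Rubisco/RuBP transition, in which case one parameter
  is weakly identified. The standard CO₂ protocol is the 12-step sequence
  400, 300, 200, 100, 50, 400, 600, 800, 1000, 1200, 1500, 1800
  µmol mol⁻¹; the duplicate 400 step is retained as two observations.
- **VPD breakpoint**: conditional on the breakpoint, the decline slope is
  closed-form, so the breakpoint is profiled on a grid and refined by
  golden-section search; the result equals an exhaustive grid search.
- **g_smax percentile rule**: observations are filtered to the optimal
  windows (800–1500 µmol m⁻² s⁻¹ PPFD, 20–30 °C, 1.4–2 kPa VPD, ambient
  CO₂ 380) and summarized as the mean of values strictly above the 90th
  percentile. The verbal rule is ambiguous between that reading and the
  percentile itself; both are implemented (`rule = "p90"`), with
  mean-above-P90 the default.

# The simulation engine

Each half-hour step: radiation (direct + 46-direction diffuse), then per
voxel two leaf classes — sunlit (direct + diffuse) and shaded (diffuse
only) — weighted by the voxel's sunlit fraction (the flux-weighted beam
transmittance reaching it). Canopy instantaneous rates are leaf-area
weighted means per unit leaf area. Daily totals are
`A_c = Σ A_h · 1800 · 10⁻³` (mmol m⁻² d⁻¹) and likewise for `E_c`
(mol m⁻² d⁻¹); `WUE_c = A_c/E_c`. Days are classed sunny above 45 and
cloudy below 15 mol m⁻² d⁻¹ of incident light; intermediate days are kept
in the output but excluded from sunny/cloudy contrasts.

The two-class sunlit/shaded treatment (rather than a full within-voxel
PPFD distribution) is the standard turbid-medium compromise; it is the
main fidelity knob of the engine and is isolated behind `simulate_step()`
so a multi-class version could be substituted.

# The scenario design

Four treatments (two interstocks × two cultivars) yield twelve runs:
S0 (a–d) pairs each treatment's own scene with its own leaf functions;
S1 (e–h) swaps leaf functions between cultivars at fixed interstock;
S2 (i–l) swaps them between interstocks at fixed cultivar. The swap is an
involution, S0 rows are bitwise identical to direct simulations, and with
identical scenes everywhere the structure effect is exactly zero — all
three identities are tested. Day-level values act as replicates; variance
is partitioned by sequential (type-I) sums of squares on the balanced
design (unbalanced data are rejected rather than silently re-weighted),
and model accuracy is graded by RRMSE (excellent < 10%, good < 20%,
fair < 30%, poor otherwise). The classical multiple-mean post-hoc is
replaced by pairwise Welch tests with Holm adjustment.

# The synthetic world

The generator's defaults are a statement of the conditions the pipeline
is meant to operate in, fixed once:

- allometry `SLA = 9·SL + 20`, `SLN = 0.35·SL + 2`, `LA = 0.62·LL²`,
  `LW = 0.7·LL + 0.2`, `PL = 0.3·LL + 0.5` (cm units) — a typical apple
  shoot bears 2–16 leaves of 15–30 cm² over the 2–40 cm shoot-length
  range, and the leaf shape factor stays inside the hexagon-feasible
  window;
- Farquhar truth V_cmax25 = 60, J_max25 = 120, R_d25 = 1.5 µmol m⁻² s⁻¹;
  Jarvis truth K = 250 µmol m⁻² s⁻¹, T_opt = 27 °C, breadth 18 °C,
  VPD₀ = 1.6 kPa, decline 0.35 kPa⁻¹ — mid-range values for apple
  genotypes, whose closure thresholds typically span ≈1.4–1.9 kPa and
  temperature optima ≈27–32 °C;
- nitrogen gradient `N_a = 0.03·PPFD_d + 1.3` g m⁻², spanning ≈1.5–2.8
  g m⁻² between deep shade and full sun;
- noise: 0.5 µmol m⁻² s⁻¹ on A–Ci observations, 0.05 on relative
  conductance, 0.5 cm² on areas;
- weather: diurnal PPFD is the sine of solar elevation rescaled exactly to
  the day's target integral (sunny 47–58, cloudy 6–13, intermediate 20–40
  mol m⁻² d⁻¹), so generated day classes agree with the classifier by
  construction; cloudy days add multiplicative half-hour noise before
  rescaling;
- crowns are ellipsoids with long shoots tied 100–120° from vertical
  (spindle training), short/bourse shoots more isotropic; long/short
  labels respect the 5 cm threshold by construction.

One master seed fans out to per-operation substreams, so every generator
is individually reproducible and independent.

What the generator does **not** emulate: woody organs (radiation sees
leaves only), within-canopy gradients of temperature, humidity or CO₂,
phenology, water stress, or the spatial autocorrelation of real shoot
positions beyond the crown envelope. A green test therefore establishes
the internal consistency of the chain — generation, fitting,
reconstruction, radiation, coupling, aggregation — not agreement with any
particular orchard.

# Numerical choices and known limitations

- Ray densities: 4 rays per voxel edge for the solar beam (8 in the
  oracle comparison), 2 for each of the 46 sky directions. Energy
  conservation is exact at any density; density only affects the spatial
  allocation among voxels (≈1% per voxel at 8 rays/edge against a 10⁵-ray
  Monte-Carlo reference).
- Grid-resolution convergence holds where the turbid-medium assumption
  does: for quasi-homogeneous (Poisson) foliage, halving the 0.3 m voxel
  edge changes whole-canopy interception by < 0.5%. For strongly clumped
  reconstructed shoots the change can reach 5–10% — a real property of
  voxel homogenization, not of this implementation; users comparing
  treatments should keep the voxel edge fixed across scenes (the engine
  does).
- Leaf-to-voxel assignment is by centroid (default); a deterministic
  area-splitting option (`method = "clip"`) exists for sensitivity
  analysis.
- Exact collinear inputs (zero-noise round trips) and noise-free ANOVA
  designs are legitimate in this package and handled explicitly: nested-F
  statistics clamp vanishing sum-of-squares differences at zero.
- Leaf-count rounding is half-away-from-zero, not banker's rounding, so
  reconstruction does not depend on IEEE rounding parity.
- The coupled root solve brackets C_i in (0, C_a + 1.6·R_d/g_s]; C_i
  above C_a is physical in the dark (respiration effluxes CO₂).
- No mesophyll conductance, no TPU limitation, no assimilation-dependent
  stomatal model (the Jarvis formulation is deliberate: conductance is
  driven by environment only), no row-to-row shading (isolated trees), no
  soil water balance, no fruit sink feedback.
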