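---
title: "Modelling soil-root water flow and tracer transport with rootflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling soil-root water flow and tracer transport with rootflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`rootflux` couples an explicit three-dimensional root architecture to soil
water flow and solute transport in a laboratory soil column, and inverts
tracer concentration maps for the root hydraulic properties. This vignette
explains the models, the assumptions behind them, the parameters that
matter, and the numerical and design choices a user should know about
before trusting (or extending) the results.

## The physical system

The virtual experiment mirrors a 7-day tracer study on a white lupin grown
in a cylindrical sand column (10 cm high, 5 cm inner diameter). For six
days the column is irrigated continuously with a 1 mmol/l solution of a
conservative, root-excluded tracer, interrupted only by nightly ~6 h
imaging windows during which irrigation and transpiration are both zero.
On the final day irrigation stops and the plant's transpiration is the only
driver of water movement, so the tracer redistributes towards the roots
that extract water. Because roots take up water but not the tracer
(*exclusion*), tracer accumulates where uptake happens; the accumulation
map is therefore an indirect observation of the root water uptake
distribution.

## Component models

### Soil water: Richards equation with van Genuchten-Mualem hydraulics

Variably saturated flow is solved on a grid of cubic voxels,

$$\frac{\partial \theta}{\partial t}
  = \nabla \cdot \left[ K(h)\, \nabla (h + z) \right] - S,$$

where $\theta$ is volumetric water content, $h$ matric head (cm of water),
$K(h)$ the unsaturated conductivity, and $S$ the root uptake sink
(cm^3^ cm^-3^ d^-1^). Retention and conductivity use the closed van
Genuchten-Mualem forms with $S_e = (1+(\alpha |h|)^n)^{-m}$, $m = 1-1/n$.
The default sand parameter set ($\theta_r = 0.03$, $\theta_s = 0.37$,
$\alpha = 0.025$ cm^-1^, $n = 5$, $K_s = 500$ cm/d, $l = 0.5$) describes a
coarse quartz sand similar to the FH31 material of the experiment; it is a
configurable placeholder, not a fitted curve.

The cylinder is voxelized by including every voxel column whose square
cross-section intersects the 5 cm disc. At the 0.25 cm voxel size this
mask over-covers the true cross-section by the factor 1.095 (1.1 at one
decimal), so every boundary water flow (irrigation, transpiration,
effluent) is multiplied by this `area_ratio` before being applied to the
simulated domain, preserving fluxes per unit area.

**Boundary conditions.** Irrigation enters as a uniform flux over the
masked surface. The lateral walls are impermeable. The bottom is the one
place where implementation experience forced a choice the problem
statement left underdetermined: with the placeholder sand parameters the
air-entry head ($1/\alpha = 40$ cm) far exceeds the 10 cm column height,
so a column standing on a free-dripping plate remains close to saturation
while effluent seeps out - which is exactly what the observed mean water
contents (~0.35 during leaching) say the real column did. A unit-gradient
"free drainage" bottom would instead drain the column to $\theta \approx
0.07$ within hours, flush the tracer through in under a day, and destroy
the spatial information in the accumulation maps. The default timeline
therefore uses a *seepage face* (saturated bottom boundary, outflow only)
while irrigation is on, and a closed bottom during scan windows and the
redistribution day. `free_drainage` remains available as an option of
`richards_step()`.

### Root water flow: a Doussan-type xylem network

Each root segment exchanges water radially with the soil and conducts it
axially towards the collar:

$$J_{r,i} = k_{r,i}\, (2\pi r_i \ell_i)\, (H_{s,i} - H_{x,i}), \qquad
  J_{x,i} = \frac{K_{x,i}}{\ell_i} (H_{x,i} - H_{x,\mathrm{parent}(i)}),$$

with $H$ total water potentials (hPa, gravity included), $k_r$ the radial
conductivity (cm hPa^-1^ d^-1^) and $K_x$ the axial conductance
(cm^4^ hPa^-1^ d^-1^). Kirchhoff balance at every node plus a collar
condition (prescribed transpiration flux during the experiment, or a
prescribed potential when measuring conductance) gives a sparse symmetric
linear system. The whole-system conductance $K_{rs}$ is the collar flux
per unit uniform soil-collar potential difference, and
$k_{rs} = K_{rs}/A_{\mathrm{root}}$ its normalization by total root
surface area (reported in m MPa^-1^ s^-1^).

Segments see the bulk potential of the voxel containing their midpoint (no
explicit rhizosphere gradient), and each segment's radial flux is
deposited into that same voxel, divided by the voxel volume, to form the
water uptake density (WUD). Splitting the flux length-weighted across the
voxels a segment crosses changes individual voxels by at most half a
segment's flux and nothing in aggregate (this bound is tested); the
midpoint rule was kept for its simplicity and because roots occupy no
explicit volume in the model anyway.

**Hydraulic parameterization.** Six parameters describe the root system:
$(k_r, K_x)$ for the taproot (T), for laterals younger than 5 days (Ly)
and for older laterals (Lo). The age threshold of 5 d splits lateral root
length into two pools of comparable size at 25 DAS. Radial conductivity
must not increase with age (casparian band maturation), so admissible
parameter sets satisfy $k_{r,Lo} \le k_{r,Ly}$. The defaults are the
optimal values of the tracer-map inversion: $k_{r,Ly} = 10^{-2}$,
$k_{r,Lo} = 10^{-3}$ cm hPa^-1^ d^-1^ and $K_{x,T} = 1$
cm^4^ hPa^-1^ d^-1^, with $K_{x,Ly} = 10^{-1}$, $K_{x,Lo} = 10^{-2}$ and a
small $k_{r,T} = 10^{-4}$ (the tracer pattern is insensitive to the
taproot's radial conductivity). We checked the alternative of making the
lateral axial conductances larger ("fully non-limiting"): it concentrates
uptake so strongly at distal tips that surface voxels are pulled to
residual water content on the final day - a stress regime outside the
study's conditions - so the moderate defaults were kept. Their partial
axial limitation is consistent with the inversion's own finding that the
old-lateral axial conductance sits below the literature range.

### Tracer transport: random-walk particle tracking

The convection-dispersion equation is solved in Lagrangian form: tracer
mass is carried by equal-mass particles moved each step by

$$\Delta \mathbf{x} = \left( \mathbf{v} + \tfrac{1}{\theta} \nabla\!\cdot\!
 (\theta \mathsf{D}) \right) \Delta t + \mathsf{B}\,\boldsymbol{\xi}
 \sqrt{\Delta t}, \qquad \mathsf{B}\mathsf{B}^T = 2\mathsf{D},$$

with pore velocity $\mathbf{v} = \mathbf{q}/\theta$ interpolated
trilinearly from the cell-centred Darcy fluxes, and the dispersion tensor
$\mathsf{D} = (\alpha_L - \alpha_T)\,\mathbf{v}\mathbf{v}^T/|\mathbf{v}| +
(\alpha_T |\mathbf{v}| + D_m)\,\mathsf{I}$. Defaults: molecular
diffusivity $D_m = 0.35$ cm^2^/d (the fixed tracer value, no extra
tortuosity factor), $\alpha_L = 0.25$ cm (the voxel width, its maximal
theoretical value) and $\alpha_T = 0.025$ cm. The Ito drift correction
$\tfrac{1}{\theta}\nabla\cdot(\theta\mathsf{D})$ - required so particles
do not pool artificially where water content or velocity vary - is
assembled once per step on the grid by central differences and
interpolated to the particles. Particles reflect at the top and at the
stair-step lateral wall (bounce-back), and leave through the bottom only
while drainage is active, feeding the effluent ledger and the breakthrough
curve. Exclusion is emergent: the sink removes water, never particles, so
concentrations rise where uptake dries the soil.

Mass bookkeeping is exact by construction: injected mass accumulates in a
`pending_mass` buffer that releases whole particles, so
`injected = in_domain + pending + exited` holds to machine precision at
all times.

## The synthetic root system generator

No architecture data accompany the study, so `generate_rsa_series()`
produces lupin-like systems whose *ensemble statistics reproduce the
printed 25-DAS measurements*: total length 3.23 m (+/- 15% across the
default band), length shares 2.4 / 27.6 / 70% for orders 1-3 (+/- 5
points), mean diameters 0.11 / 0.06 / 0.045 cm, branching densities 4.8
and 3.3 laterals per cm of parent, elongation rates 0.43 / 0.16 / 0.17
cm/d, and 79% of root length in the top 3 cm.

The generator grows a taproot from the collar at sowing, inserts order-2
primordia along it as a depth-biased Poisson process (e-folding depth
1.8 cm, calibrated once against the 79% top-3-cm fraction), and order-3
primordia uniformly along order-2 axes. Emergence is acropetal with a
stochastic delay: parent-node creation time + 1 d + an exponential extra
delay (means 2 d and 5 d for orders 2 and 3). The delay spread is what
makes "young segments near the tips" and a roughly even split of lateral
length across the 5-day age threshold *emerge* rather than being imposed;
a purely deterministic 1-day lag was tried first and provably cannot give
the observed young/old balance at 25 DAS. Placement intensity is inflated
by the inverse emergence probability so that the *realized* branching
density at the horizon matches the configured density despite thinning.

Axis growth durations are derived from the printed mean root lengths
(mean length / elongation rate), inflated by per-order censoring
adjustments (1.1, 1.15, 1.9) that offset the fact that axes still growing
at 25 DAS pull the realized mean below the mature axis length. These
adjustments were calibrated once against the printed means and are not
free tuning knobs of the experiments.

What the generator does *not* emulate: root growth responses to soil
moisture, tropisms beyond simple wall/bottom deflection and a gravitropic
bias, the <200 um roots invisible to the imaging, and co-registration
error between root and tracer maps. Tests passing on these twins therefore
validate the *model chain and its statistics*, not image segmentation or
registration robustness.

## Experiment timeline and flux magnitudes

`generate_timeline()` splits each day into a 12 h light window (plant
transpires at a demand that ramps linearly from half of peak at 18 DAS to
peak at 25 DAS - the observed doubling), a 6 h scan window (all fluxes
zero) and a dark remainder (irrigation on during leaching). The absolute
magnitudes are not printed as a table, but the main text pins them well
enough: mean water contents of 0.36 at 19 DAS and 0.21 at 25 DAS imply
~29 cm^3^ transpired on the final bottom-closed day, giving the default
daytime peak demand of 60 cm^3^/d (daily volumes of ~15 to ~29 cm^3^/d
over the week); irrigation defaults to 35 cm^3^/d so that the column stays
wet through the leaching phase and the tracer front crawls down the
column, matching the late observed breakthrough. Both are configurable.

## Virtual observation, proxies and inversion

`observe()` block-averages fine fields to merged voxels (default 0.5 cm,
the comparison resolution of the study) and can add Gaussian noise whose
standard deviation inflates proportionally above 5 mmol/l, mimicking the
larger uncertainty of imaging-derived concentrations at high values;
negative draws clip at zero and are counted. The initial tracer field for
runs starting mid-experiment is built from a total-mass constraint:
xy-uniform, decreasing linearly with depth over the imaged region and
uniform below it (`build_initial_concentration()`), integrating exactly to
the prescribed mass.

Proxy analysis compares, per voxel over a window, water depletion
$WD = \theta(t_1)-\theta(t_2)$ and tracer accumulation
$Acc = c(t_2)-c(t_1)$ against the cumulative uptake density, each
normalized to unit sum ($\hat Y_i = Y_i / \sum_j Y_j$). Agreement is
scored by squared Pearson correlation in 3-d at merged resolution and in
1-d on horizontally averaged depth profiles.

The inversion scores each admissible hydraulic parameter set by the RMSE
between simulated and observed maps over the jointly observed merged
voxels, on geometric parameter sequences within
$[10^{-5}, 10^2]$ cm hPa^-1^ d^-1^ (radial) and $[10^{-4}, 10^2]$
cm^4^ hPa^-1^ d^-1^ (axial). `grid_search()` evaluates all scenarios
(order-independent; ties broken by lowest scenario index; failed forward
runs are flagged, not fatal) and `local_refine()` re-grids around the
incumbent on intervals that halve in log space until the relative
improvement drops below 10^-3^. `sensitivity_cross_sections()` evaluates
2-d factor lattices (default 1/8 to 8) around an optimum;
`flat_directions()` flags a parameter as insensitive when its whole-axis
RMSE range is below a tenth of the largest range over all parameters, a
threshold chosen to sit well above the Monte-Carlo noise floor of the
particle method and well below any physically meaningful response.

## Numerical choices

* **Richards solver.** Mixed-form (theta-h) finite volumes, backward
  Euler, modified-Picard iteration with tolerance 10^-6^ on the
  water-content increment and at most 15 iterations; on failure the step
  halves (the solver also grows steps 1.5x after successes). After
  convergence the water content is updated from the converged face fluxes
  - making every step exactly mass conservative - and heads are re-derived
  from the retention curve so the two fields can never drift apart (early
  development showed that keeping the Picard heads lets dry cells run away
  to unphysical values). The sparse system is symmetric positive definite;
  its symbolic Cholesky factorization is computed once per grid and
  reused, which cuts run time roughly threefold.
* **Sink coupling.** Within a coupling step the xylem system is re-solved
  whenever the current sink would remove more than a third of any voxel's
  extractable water, so uptake shifts away from drying voxels
  (compensation) instead of crashing the soil solver.
* **Common random numbers.** Particles advance once per outer coupling
  step using the time-weighted mean Darcy flux of that step and a
  substep count quantized to powers of two. Runs that differ only in root
  hydraulic parameters therefore consume identical random-number streams,
  so RMSE differences between scenarios measure physics, not Monte-Carlo
  resampling (without this the sensitivity surfaces at desk-scale particle
  budgets are dominated by a ~4 mmol/l noise floor).
* **Degenerate inputs.** Empty root systems, zero-sum normalizations,
  all-zero radial conductivities under flux control, non-divisible merge
  widths, negative fluxes and out-of-domain segments all raise immediate,
  specific errors rather than propagating NaNs.
* **Problem sizes.** The bundled experiments run on a 0.5 cm grid (~1,500
  active voxels, 20 layers) with 8,000-20,000 particles and a 0.05 d
  coupling step; a full 7-day coupled run takes about a minute on one
  core. The 0.25 cm grid of the original study is supported
  (`build_column_grid(dx = 0.25)`) and reproduces the printed 1.1 area
  ratio; the coarser default was chosen so the complete test suite and the
  twin inversions stay cheap. Inversion and sensitivity runs use the final
  redistribution day with an initial tracer profile from the total-mass
  constraint, mirroring how the original optimization used only the last
  experimental phase, where root properties dominate the signal.

## Known limitations

* The soil is homogeneous: the preferential-flow pathways that the study
  holds responsible for late-time breakthrough mismatch are intentionally
  out of scope, so simulated breakthrough lags observations by design.
* Soil hydraulic and flux-magnitude defaults are placeholders constrained
  by main-text values only; users with the supplementary parameter tables
  should override them in the configuration.
* The xylem network has no osmotic coupling, aquaporin dynamics or growth
  feedback beyond the age classes; collar demand is always met
  (flux-controlled), so severe water stress is outside the model's domain.
* Virtual observation adds resolution loss and optional Gaussian noise but
  no imaging physics (no relaxivity calibration, no segmentation error).
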