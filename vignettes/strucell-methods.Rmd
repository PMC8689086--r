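---
title: "Methods: structured microenvironments, depth-averaged flow and simulated single-cell stress exposure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structured microenvironments and single-cell stress exposure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`strucell` reconstructs, as a fully synthetic pipeline, the computational
toolchain of microfluidic experiments on stress sensing by individual
yeast cells in structured environments: rasterised device geometries, a
depth-averaged flow model, Voronoi/distance-map spatial metrics, and a
calibrated generator of single-cell copper-reporter responses. This
vignette records the models, their assumptions, the tunable parameters,
and the numerical and design choices a maintainer would want to know
about — including what the synthetic data can and cannot say about real
experiments.

## 1. Scenes and geometry generators

A *scene* is a binary obstacle raster (default 0.5 µm pixels, so 4-µm
microspheres are resolved by 8 px) with physical scales, an analysis
region, and cell positions. Flow always runs top to bottom. Invariants
checked on every generated scene: open inlet and outlet pixels, an open
4-connected inlet→outlet path, cells on open pixels inside the analysis
region. Cells are used for placement clearance only; they never enter
the obstacle mask seen by the flow solver, because the flow model is
computed from device structure alone with cells overlaid afterwards.

Three generators emulate the experimental systems:

* **Mock arrays** — a central cell with up to eight discs whose nearest
  surface sits exactly one or two object-diameters from the cell centre.
  Placement is deterministic (clockwise from north, centres snapped to
  the pixel grid) so identical specifications give identical masks; the
  metric trends depend on counts and spacing, not compass order.
* **Trap chambers** — 100 × 100 µm trap interiors bounded by a perimeter
  of 4-µm square pillars with 6-µm gaps (the layout is not published;
  this choice retains a 4–5 µm cell while leaving open flow paths).
  Sphere counts per trap are drawn from a normal truncated at zero
  (means 0/16/39, sd 0/5/8 in the study conditions); spheres are placed
  uniformly in the interior without overlap; one cell per trap. Real
  microspheres aggregate near trap openings; uniform placement is the
  simplest defensible null and produces *stronger* area reductions
  (~20–50-fold) than the published 7–12-fold — analyses that depend on
  the fold-reduction magnitude, rather than its direction, should bear
  this in mind.
* **Micromodels** — a 1 mm wide channel (default 2 mm long, about one
  fifth of the physical device) filled with randomly oriented,
  possibly overlapping ellipses (axes 15–60 µm) until a target porosity
  (default 0.55) is reached, with small obstacle-free margins at inlet
  and outlet. This is a statistical stand-in: the published pore layout
  is not reproduced, only its scale and character. Dense packings can
  occasionally block the channel; the generator redraws (bounded, within
  the seeded stream) until the connectivity invariant holds.

## 2. The depth-averaged flow model

Between the thick limit (2-D Stokes in the plane) and the thin
(Hele-Shaw) limit, the vertically averaged velocity obeys the
interpolated momentum equation

$$\nabla p = \mu \nabla^2 \bar v - \frac{12\mu}{h^2}\,\bar v,
\qquad \nabla\cdot\bar v = 0,$$

which reduces to the correct equations in both limits. Assumptions
inherited from the experimental operating point: Newtonian medium (the
mild shear thinning of the medium changes viscosity by less than 2×
over the relevant shear rates and is neglected), negligible inertia
(Re ~ ρΦ/(µh) ≈ 10⁻²), incompressibility. Boundary conditions: no slip
on obstacles and side walls; uniform normal speed
$v_0 = \Phi/(h\,w)$ = 1.78 × 10⁻⁵ m/s at the inlet (an average-velocity
inlet condition gives no visible difference); zero gauge pressure with
zero-gradient outflow at the outlet.

**Discretisation.** Staggered (MAC) finite differences: pressures at
pixel centres, velocities on faces — this avoids pressure checkerboards
and places no-slip walls on pixel boundaries with reflecting tangential
ghosts. Obstacles are staircase; with default pixels, typical pores are
≥ 14 px across. Equations are assembled in lattice units (lengths in
pixels, velocity in units of $v_0$, pressure in units of $\mu v_0/\Delta x$)
for conditioning, giving a single drag coefficient $12(\Delta x/h)^2$.

**Solver.** Cell-wise damped Vanka (coupled Gauss–Seidel) smoothing in a
geometric multigrid V-cycle (full-weighting/bilinear MAC transfers,
rediscretised coarse operators on any-child-fluid coarsened masks),
used as a preconditioner inside BiCGStab on the full saddle-point
system. Pure multigrid converges quickly on open channels but the
rediscretised coarse operators degrade near dense staircase obstacles;
the Krylov wrapper restores robust convergence (10⁻¹⁰ residuals on all
oracle problems). Open regions with no inlet–outlet path carry no flow
and no well-defined pressure and are excluded from the linear system.
Convergence is declared on the maximum momentum and continuity
residuals (lattice units); non-convergence raises an error with the
residual report.

**Verification.** The empty straight channel admits the closed form
$v(x) \propto 1 - \cosh(\sqrt{12}\,x'/h)/\cosh(\sqrt{12}\,w/2h)$; the
suite checks the mid-channel profile against it at 4 px per channel
height, and recovers the plug (thin) and parabolic (thick, peak/mean
→ 3/2) limits. Profile comparisons exclude pixels within one
boundary-layer width $h/\sqrt{12}$ of the side walls: the staircase
scheme is second-order (errors 4.5%/1.7%/0.5% at 4/8/16 px per h when
the wall pixel is included) but the first half-pixel of an
under-resolved boundary layer cannot be compared pointwise at 2%.
Mass conservation is checked by integrating fluxes through transverse
stations; on a full-scale 1 × 2 mm micromodel at 0.5 µm pixels the
measured station-to-station spread is ~10⁻⁷ (relative) at tight
tolerance and scales linearly with the solver tolerance, so the
conservation check in the test suite runs at a 10⁻³ lattice tolerance —
leaving two orders of margin on its 1% criterion while keeping the run
inside a desk-scale budget. Problem sizes used by the tests: oracle
channels up to 256 × 320 px, conservation on the full 2000 × 4000 px
channel, everything else ≤ 500 × 1000 px.

**Exposure summary.** Copper reaches a cell by diffusion across a
neighbourhood of radius $r \approx D/v$; with D = 7 × 10⁻¹⁰ m²/s and the
typical pore speed 10⁻⁴ m/s (asserted, not derived — the default
neighbourhood radius inherits this assertion) this is ≈ 7 µm. Per-cell
exposure is the mean depth-averaged speed over open pixels within that
radius; cells adhere to walls and floors where the local speed is
near zero, so the neighbourhood mean, not the point value, is the
relevant proxy.

## 3. Spatial metrics

Every open pixel of the analysis region is assigned to its nearest
particle: cells are point generators; each 4-connected obstacle
component is an extended generator whose distance is the exact
Euclidean distance to its nearest pixel (a Felzenszwalb–Huttenlocher
exact transform; chamfer approximations would corrupt the linear
weighting). Ties go to cells, then to the lowest cell id — deterministic
because squared integer distances are compared exactly. Obstacle
components wholly outside the analysis region do not generate: in a
trap, the pillar ring bounds the region instead of eating it from the
rim, which is what makes the sphere-free trap a single ~10⁴ µm² cell
region, consistent with the area scale over which response saturation
is observed. Grey weights are distance-from-centre + 1 (centre pixel 1,
200 px away → 201), kept at full precision and clamped to 0–255 only
for 8-bit renders. The median of an even-sized sample is the
lower-middle order statistic, matching integer image-histogram medians.
One worked subtlety: a pixel *adjacent* to the centre weighs √2 + 1 or
2, not 1 — the weighting is anchored at the centre pixel itself, which
is the only reading consistent with the 200 px → 201 example.

## 4. The response generator

Expected reporter fluorescence is linear in copper over 25–300 µM with
a larger first step out of the basal state (0 → 25 µM exceeds
subsequent 25 µM increments) and a ≥ 1 multiplier for 2 h versus 1 h
exposure. Absolute fluorescence units are arbitrary; only ratios, CVs
and correlations carry meaning. Cell-to-cell noise is multiplicative
lognormal with $\sigma^2 = \ln(1 + \mathrm{CV}^2)$ — a truncated normal
cannot produce the observed CVs above 100% on positive support.

Exposure presets:

* `micromodel_uncoupled` — constant expected percent increase; the
  soil-micromodel regime in which neither spatial metrics nor flow
  predict single-cell response.
* `cellasic_area` (area-coupled) — expected percent increase is a
  logistic in Voronoi area with midpoint 4500 µm² and width
  1500/ln 9 ≈ 683 µm², so the 10–90% rise spans 3000–6000 µm² and the
  response is flat above the window; the floor is 15% of the ceiling,
  fixing the mean suppression of sphere-laden conditions at ~85%
  (within the observed 80–90%). Only monotonicity, the window and two
  aggregate contrasts constrain this curve; the exact shape is
  otherwise unconstrained and the logistic is a convention.
* `cellasic_flow` (flow-coupled) — expected response ∝ (neighbourhood
  speed)^α with α = ln(1 − 0.34)/ln 0.5 ≈ 0.599, fixed once from the
  single published constraint (halving flow cuts the mean response by
  ~34%).

**CV calibration.** The published heterogeneity numbers are *sample*
CVs at small n (59/58/62 cells per trap condition, 103 in the
micromodel). The moment estimator of a lognormal CV is biased downward
at such n, saturating near 300–450% regardless of the population value,
so population CVs are calibrated by simulation such that the expected
sample CV at the study's n reproduces the printed number (63% → 64.6%,
53.7% → 54.3%, 202% → 299%), and for the densest trap condition the
anchor is additionally refined against the full generative pipeline
(trap ensembles with their realised area spread and the log-log CV
interpolation between anchors), landing at an anchor of 8500% at the
condition's mean area of 188 µm². The calibration script is
`inst/calibration/calibrate_presets.R`; its outputs are frozen
constants. The CV-versus-area anchors decrease monotonically, so binned
CV falls with Voronoi area as observed. Recovery tests assert the
moment estimator for the moderate presets (where it converges by
n = 10⁴) and the log-scale σ — exact at any n — for the heavy-tailed
anchors.

## 5. Statistics

Sample statistics use the n−1 denominator throughout (the study does
not state its convention; this is the standard for small biological
samples). Pearson r carries a two-sided p from the t transform with
n − 2 df; binning of Voronoi areas uses half-open 1000 µm² intervals
from zero with values on an edge assigned upward; SEM is sd/√n. These
primitives are hand-written (they are part of the package's surface)
and cross-checked against `cor.test`, `lm` and grouped recomputations
in the tests. One-way ANOVA with Tukey comparisons, used in the
original analyses for condition contrasts, is deliberately delegated to
`aov`/`TukeyHSD` and not re-implemented.

## 6. Reproducibility and problem sizes

Every stochastic function takes a seed; pipeline stages derive seeds
from the master seed by hashing the stage name, so stages can be re-run
in isolation. Identical configurations produce byte-identical output
tables. The test suite runs the pipeline on reduced geometries
(150–300 µm channels, ~tens of cells, 12–24 traps); study-scale runs
(1 × 2 mm channel at 0.5 µm pixels, 179 traps, 10⁵-cell flask
populations) are exercised by the acceptance checks and
`scripts/acceptance.R`.

## 7. Known limitations

* The synthetic micromodel shares scale and porosity with the physical
  device, not its actual pore network; per-geometry conclusions do not
  transfer.
* Uniform sphere placement overstates the Voronoi-area reduction in
  sphere-laden traps relative to the clumped reality (~20–50-fold vs
  7–12-fold); contrasts that only need the direction and a ≥ 7-fold
  magnitude are unaffected.
* The published summary statistics for the trap experiment are not
  jointly representable by any simple noise model: with ~85% mean
  suppression and per-condition CVs of 63/202/377%, the pooled
  area–response Pearson correlation across the 179 cells is ≈ 0.55–0.6
  in the calibrated generator (the between-condition separation
  dominates), versus the published 0.280 (caption; 0.237 in the text of
  the same analysis). The package keeps the printed CVs and suppression
  as calibration targets and documents that the pooled r of the
  synthetic ensemble is higher; the corresponding acceptance check is
  expected to fail and is retained as a record of the discrepancy.
* The flow model is depth-averaged and steady; it does not resolve
  vertical structure, transients, or the copper advection–diffusion
  field itself (scale analysis stands in for transport).
* Passing tests demonstrate internal consistency and faithfulness to
  the published summary statistics — not predictive validity for real
  structured environments, where adhesion, growth, uneven illumination
  and segmentation noise all enter upstream of these models.
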