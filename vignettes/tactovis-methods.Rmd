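---
title: "Methods: models, geometry and statistics behind tactovis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, geometry and statistics behind tactovis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tactovis)
```

`tactovis` bundles three computational analyses of tacto-visual
integration in mouse primary visual cortex (VISp): a rate model of
cross-modal suppression, a 3D whisker-array / visual-field overlap
simulation, and spatial statistics for cell-position data. This vignette
explains each model, its assumptions, the tunable parameters and their
defaults, the numerical choices, and what the synthetic-data generators
do and do not emulate.

## The two-population rate model

Whisker touch suppresses visually evoked activity in VISp. The circuit
hypothesis is feedforward inhibition: long-range excitatory input from
barrel cortex (SSp-bfd) reaches both pyramidal neurons (PN) and
fast-spiking interneurons (FS) in VISp with similar synaptic strength,
but only the FS population — with its lower activation threshold and
higher firing gain — is driven to spike, and its inhibition then pulls
down PN activity. The model is a Wilson–Cowan-type pair of
threshold-linear populations,

$$
\tau_P \dot A_P = -A_P + f_P(J_{PP}A_P - J_{PF}A_F + I^{cm} + I^v_P),\qquad
\tau_F \dot A_F = -A_F + f_F(J_{FP}A_P - J_{FF}A_F + I^{cm} + I^v_F),
$$

with $f_i(h) = G_i\,[h-\theta_i]_+$ and the cross-modal drive capped at
$\rho = \delta\,\theta_P$:
$I^{cm} \leftarrow \max(\min(I^{cm}, \rho), 0)$. The cap encodes the
empirical observation that tactile input alone depolarizes but never
fires PNs; with $\delta \le 1$ the capped drive is subthreshold for PN
by construction.

Default parameters (`network_params()`): $\tau_P = 60$ ms,
$\tau_F = 12$ ms, $G_P = 1$, $G_F = 5$, $J_{PP} = 2$, $J_{PF} = 4$
(I/E weight ratio $\alpha = J_{PF}/J_{PP} = 2$), $J_{FF} = 0.8$,
$J_{FP} = 0.4$, $\theta_P = 0.5$, $\theta_F = 0.35$, $I^v = (3.6, 0.6)$,
$I^{cm} = 0.6$, $\delta = 1$. These reflect the physiology: FS cells
have roughly fivefold higher gain, a ~30 % smaller distance from rest to
spike threshold, and receive equal-amplitude cross-modal input.

When both populations are above threshold the dynamics are linear and
the fixed point is available in closed form with effective weights
$w_{ij} = G_i J_{ij}$, drives
$\varepsilon_i = G_i(I^{cm} + I^v_i - \theta_i)$ and
$\varphi = w_{FP}w_{PF} - (w_{PP}-1)(w_{FF}+1)$:

$$
A_P^* = \frac{(1+w_{FF})\varepsilon_P - w_{PF}\varepsilon_F}{\varphi},\qquad
A_F^* = \frac{w_{FP}\varepsilon_P - (w_{PP}-1)\varepsilon_F}{\varphi}.
$$

The suppression induced by adding the capped drive is

$$
\Delta A_P^* = I^{cm} G_P\,[1 + G_F(J_{FF}-J_{PF})]/\varphi, \qquad
\Delta A_F^* = I^{cm} G_F\,[1 + G_P(J_{FP}-J_{PP})]/\varphi,
$$

independent of the visual drive as long as the network stays active.
With the defaults: $\varphi = 3$, visual-only fixed point
$(3.5, 1.65)$ Hz, combined $(1.0, 1.15)$ Hz, suppression
$(-2.5, -0.5)$ Hz, and an FS-only rate of $0.15$ Hz under cross-modal
drive alone.

```{r network}
p <- network_params()
steady_state_analytic(p, "v")
steady_state_analytic(p, "v+w")
suppression_analytic(p)
classify_regime(p)
```

The regime report evaluates the three inhibition-stabilized-network
(ISN) criteria — (I) $G_P J_{PP} > 1$, (II)
$G_F J_{FF} + 1 > k\,(G_P J_{PP} - 1)$ with $k = \tau_F/\tau_P$, (III)
$\varphi > 0$ — and the two suppression conditions
($1 + G_F(J_{FF}-J_{PF}) < 0$ for PN, $1 + G_P(J_{FP}-J_{PP}) < 0$ for
FS, each together with $\varphi > 0$).

### Numerical choices

* **Integrator.** Forward Euler at `dt = 1e-4` s. Only the step size is
  prescribed by the modeling conditions we reproduce; Euler is the
  simplest scheme consistent with that step, and the dynamics are not
  stiff at the default time constants (`dt`/$\tau_F$ ≈ 0.008). Because
  the fixed point of the Euler map coincides exactly with the ODE fixed
  point, converged simulated steady states match the closed form to
  floating-point accuracy, far inside the 1e-6 Hz equivalence the tests
  require. A convergence check (relative change below 1e-9 over the
  0.1 s before each stimulus transition) can be enabled with
  `check_convergence = TRUE`.
* **Transfer boundary.** $f_i(h) = 0$ at $h = \theta_i$ exactly (the
  inactive branch is closed at the threshold).
* **Validity is verified, never assumed.** The closed form is the
  active-branch solution; `steady_state_analytic()` re-derives the input
  $h_i$ at the computed fixed point and reports `valid = FALSE` whenever
  either population is at or below threshold, rather than silently
  returning the formula.
* **Degeneracy.** $\varphi = 0$ (no unique active fixed point) raises a
  degenerate-network error; parameter sweeps record the error per grid
  point and continue.
* **Paradoxical-effect probes.** Inside the ISN regime a small extra
  drive to FS lowers both steady-state rates; this is verified both
  analytically and by simulation. When ISN criterion III is violated
  ($\varphi < 0$) the active fixed point is a saddle, so forward
  simulation cannot reach it; the rise of $A_F^*$ in that regime is
  therefore asserted on the closed form, and the dynamically stable
  non-ISN case (criterion I false) is additionally verified by
  simulation. For the cm-only condition the visual drives are set to 0
  with thresholds and weights unchanged.
* **Random draws in property tests** are log-uniform multiplicative
  perturbations of the default set over $[0.1, 10]$ (narrower,
  $[0.5, 2]$, where simulation is involved), rejecting draws whose
  fixed points fail the activity checks; all seeds are fixed in the
  tests. Draws whose linearized dynamics violate the Euler stability
  bound at the fixed step are excluded from simulation-based checks —
  the property under test concerns the converged fixed point, not the
  integrator's stability region.

## Whisker-array geometry

The geometry module asks how much of the visual field covered by VISp is
also reachable by the whiskers. All computations run on synthetic
arrays from `gen_whisker_array()`: 24 whiskers (rows A–E × arcs 1–4 plus
the caudal greek column α–δ) on a parametric mystacial pad, with
arc-length and emergence-angle schedules plus seeded jitter.

Conventions, used everywhere: right-handed head frame with x nose-ward,
y toward the left-lateral side, z up; the horizontal plane is parallel
to the bregma–lambda plane. Azimuth is measured from the nose-ward axis
in the horizontal plane (positive toward the left/caudal side),
elevation from the horizontal plane (positive up). The twist angle
$\zeta_w$ orients the curvature plane: 0° ventral, 180° dorsal, +90°
rostral, −90° caudal.

* **Whisker shape.** Each whisker is a constant-curvature planar arc of
  exact arc length, sampled as a 50-point polyline. Real whiskers curve
  approximately in one plane; a circular arc is the simplest planar
  shape with exact length bookkeeping (the chord-length invariant holds
  by construction), and curvature magnitude is a generator parameter.
* **Whisking planes.** For each row a total-least-squares plane is
  fitted through the row's basepoints and tips (SVD of the centered
  coordinates). Its normal is the retraction/protraction rotation axis;
  the in-plane mean base-to-tip direction defines the axis for
  inclination changes. The normal is oriented so that positive in-plane
  rotation moves tips rostrally (protraction). Greek whiskers ride with
  the plane of their corresponding row.
* **Scenario order.** Incline planes → rotate in plane (±40°
  retraction/protraction) → roll, matching the simulated whisking
  narrative in which row-specific roll (A −36.8°, B −14.0°, C 23.8°,
  D 16.2°, E 26.7°, scalable ×0.5/×1/×2) is applied after protraction
  about each whisker's base-to-tip axis. Roll angles are only known for
  rows A–E; greek whiskers use their host row's angle (an assumption,
  flagged here).
* **Eye and visual field.** The left-eye center is a generator
  parameter (the reference head model pins it only up to alignment);
  overlap results are reported relative to that choice. The VISp
  coverage polygon spans 0–90° azimuth and −25° to +60° elevation; eye
  movements are modeled by dilating the polygon 20° in every direction.
  Dilation is implemented as a distance test in (azimuth, elevation)
  degree space — a point is inside the dilated polygon iff it is inside
  or within 20° of the outline — which is exact buffered-polygon
  membership for a simple polygon; the angular domain is well under a
  hemisphere, so planar treatment is acceptable and spherical buffering
  is out of scope. Tips exactly on the boundary count as inside.
* **Tip uncertainty.** Measurement uncertainty is propagated by
  rebuilding each whisker with ±2° on the emergence angles and ±4° on
  the twist angle; each source contributes the mean tip displacement of
  its ± pair, the three sources combine in quadrature, and a 0.5 mm
  basepoint uncertainty is added. The tests compare the resulting
  radius against a Monte-Carlo oracle — the maximum tip displacement
  over $10^4$ uniform draws in the angle box, plus the same floor —
  which is the smallest sphere containing the perturbed tips, the
  quantity the quadrature sum approximates (the corner of the box);
  agreement within 25 % is required. Across-animal summaries add the
  s.e.m. over arrays linearly to the propagated radius.

What the generator does *not* emulate: real traced whisker shapes
(tapering, intrinsic torsion), dynamic whisking trajectories, and the
photogrammetric reconstruction pipeline. Overlap fractions from the
synthetic array are therefore qualitative: the tests assert the
direction of the effect (protraction ≥ retraction) and isometry/
uncertainty invariants, not the study's measured percentages — those
depend on the real whisker and retinotopy data. With the default
generator the fractions happen to fall near the measured ones (~40 %
retracted, ~80 % intermediate, 100 % protracted at 20° dilation), but
no test pins them.

## Spatial statistics

* **PCA axes** (`pca_axes()`) use `stats::prcomp` on the 2D-projected,
  pooled cell positions (pooling across animals first is the default;
  per-animal analysis can be run by subsetting). Axes are sign-fixed
  (non-negative x-component, ties toward +y) so repeated runs are
  reproducible.
* **Parcellation** (`parcellate()`) draws section lines with the slope
  of PC2, spaced exactly 200 units apart along PC1 and anchored at the
  minimum PC1 score; an optional second family along PC2 forms the
  cross grid. Cells exactly on a line belong to the lower-score side;
  vertical slopes are handled in parametric point+direction form, so no
  division by zero occurs. The number of parcels emerges from the data
  extent and the spacing; it is not a fixed constant.
* **Density maps** (`density_map()`) evaluate a Gaussian KDE with the
  full data covariance and Scott's factor $n^{-1/6}$ on a uniform grid
  of step 58 units (≈ 200/√12, so roughly twelve grid cells per
  parcel), padded by 3 marginal bandwidths per side to relax edge
  effects on the contours; the padding is cut off after evaluation.
  The grid is laid out symmetrically around the data midpoint so that
  mirror-symmetric inputs produce exactly mirror-symmetric fields.
  Near-singular covariances fall back to a small jitter with a warning.
* **Barrel enrichment** (`barrel_fraction_index()`,
  `barrel_permutation_test()`): the relative fraction index
  $fr_b = (\#\mathrm{Cells}_b/\#\mathrm{Cells}_{tot}) \times
  (\#\mathrm{Area}_{tot}/\#\mathrm{Area}_b)$ uses the total cell count
  over both layers (putting layers on a common scale) and pixel areas
  over the whole depicted field, septa included. The null repositions
  all of a layer's cells uniformly over the rectangular field support
  2500 times (uniform-over-barrel-pixels is available via `support`);
  the one-tailed empirical p-value uses the add-one rule, so it is
  never zero and is super-uniform under the null. Multiplicity is
  handled per the published convention by the strict per-barrel
  α = 0.001; a max-statistic family-wise mode is available via
  `correction = "max-stat"` for users who prefer explicit FWER control.
* **Visual-space assignment** (`parcel_visual_coverage()`) maps parcel
  outlines through a retinotopy and weights each patch by its parcel's
  cell fraction; parcels reaching the 5 % fraction threshold form the
  merged coverage region. The merged region is returned as the list of
  selected patches plus a membership predicate (union of patches) —
  an explicit union ring is not constructed, and the tests validate the
  region against a brute-force grid preimage oracle.

The cloud/barrel generators produce Gaussian clouds with a configured
axis and variance split, and elliptical barrels with per-barrel
enrichment factors, so every statistical routine is tested against
known ground truth. They do not emulate atlas registration error,
detection noise, or laminar structure beyond labels.

### Problem sizes used in the test-suite calibrations

Calibration of the permutation test uses 200 runs of 2000 uniform cells
over 20 barrels at the full 2500 shuffles (nominal α = 0.05, observed
type-I rate required in [0.03, 0.07]); power uses 100 runs with one
5× enriched barrel at α = 0.001 (≥ 95 % detection required). PCA
recovery uses $10^4$-point clouds (axis within 2°, split within
±0.03). Lighter versions of the same checks (fewer runs and shuffles)
run alongside the unit tests. These sizes give the calibration
estimates standard errors well below the decision margins.

## Known limitations

* Two populations, no spiking, no plasticity: the rate model speaks to
  mean activities; spiking-network questions (connectivity motifs,
  synchrony) are out of scope.
* The geometry is synthetic; quantitative overlap percentages inherit
  the generator's pad, eye and retinotopy choices.
* The permutation null treats cells as independently repositioned
  points; clustering within animals is not modeled.
* Polygon operations are planar in degree space; distortion near the
  poles is negligible for the VISp field but the code should not be
  reused for fields approaching a hemisphere.
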