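---
title: "A 3D vertex model of epithelial folding: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A 3D vertex model of epithelial folding: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epifold)
```

## The model

epifold simulates a columnar epithelium — the *Drosophila* wing imaginal
disc is the motivating system — as a three-dimensional vertex model. Tissue
geometry is a fixed-topology polygonal complex: each cell has an apical and
a basal polygonal face built from paired vertices, lateral quadrilaterals
connect the two, and the tissue is periodic in the two lateral directions
(free in z, with z pointing from basal to apical). The mechanical work
function is

$$
W = \sum_c T_a A_a^c + \sum_c T_b A_b^c + \sum_{f \in \mathrm{lat}} \bar T_l A_f
  + \sum_{e \in \mathrm{ap}} \bar\Lambda_a L_e + \sum_{e \in \mathrm{ba}} \bar\Lambda_b L_e
  + \sum_{i \in \mathrm{ba}} \tfrac{k}{2}\,\lvert x_i - X_i^{\mathrm{ref}} \rvert^2
  + \sum_c \tfrac{K_V}{2}\,\frac{(V_c - V_0)^2}{V_0},
$$

with surface tensions $T_a, T_b, T_l$ on apical, basal and lateral faces,
junctional edge tensions $\Lambda_a, \Lambda_b$ on apical and basal
cell–cell edges, elastic springs of stiffness $k$ anchoring each basal
vertex to its position in the relaxed reference state (the extracellular
matrix attachment), and a stiff quadratic penalty enforcing cell volume
conservation. Elements shared by two cells (lateral faces, junctional
edges) carry the *mean* of the two adjacent cells' parameters and are
counted once; this makes "increase the lateral tension of a cell stripe"
well defined at the stripe boundary.

Forces are the exact analytic gradient of $W$. Faces are fan-triangulated
about their centroid, and cell volumes use the divergence theorem over the
*same* triangulation, so the volume-penalty gradient is consistent with the
areas — the package tests verify the gradient against central finite
differences at relative error below $10^{-6}$.

### Units and parameters

Everything is nondimensional: the tension unit is the reference apical
surface tension and the length unit is $V_0^{1/3}$ (unit cell volume).
The defaults encode the calibrated baseline:

| parameter | default | meaning |
|---|---|---|
| `T_a` | 1 | apical surface tension (the unit) |
| `T_b` | 4 | basal surface tension, four times apical |
| `Lambda_a` | 1 | apical edge tension; the normalized value $\Lambda_a/(T_a V_0^{1/3})$ is a free parameter set to 1 |
| `Lambda_b` | 4 | basal edge tension, four times apical |
| `k` | 1 | ECM spring constant; normalized $k V_0^{1/3}/T_a = 1$ is the second free parameter |
| `T_l` | calibrated | lateral surface tension (see below) |
| `K_V` | $2 \times 10^4$ | volume-penalty stiffness (implementation parameter) |
| aspect ratio | 5 | columnar height / equivalent diameter before folding |

The basal:apical ratio of 4 comes from recoil-velocity measurements after
edge ablation (basal recoil 3–5 times apical); the two normalized free
parameters are set to 1, and the test suite includes a sensitivity sweep
showing the fold readouts vary smoothly, not qualitatively, within a
reasonable range around them. The pre-fold aspect ratio is exposed in the
configuration rather than hard-coded, since its exact measured value is a
calibration input, not a model constant.

### Lateral tension calibration

With a fixed periodic box the flat aspect ratio is purely geometric, so
`build_hex_tissue()` does two things: it sizes the box so the requested
aspect ratio holds exactly, and it calibrates $T_l$ so that the same
packing is *in-plane stress free* — along the constant-volume
regular-prism family the per-cell energy
$W(a) = (T_a+T_b)\tfrac{3\sqrt3}{2}a^2 + 3(\Lambda_a+\Lambda_b)a +
\tfrac{2 T_l V_0}{\sqrt3 a}$ is stationary at the built hexagon side $a$.
This makes the chosen aspect ratio a mechanical property of the parameter
set rather than a box artefact. Box dimensions are held fixed throughout —
also during ramps. Because the baseline box is calibrated to be stress
free, letting it relax would leave the flat state unchanged; during
folding a fixed box mirrors the fixed periodic frame of the reference
simulations, and confinement effects are limited to a weak in-plane
prestress of the folded stripe.

### Volume conservation

Volume conservation is a stiff penalty rather than a Lagrange multiplier:
it is robust with quasi-Newton minimizers and the violation is monitored at
every accepted step. With the default $K_V = 2\times10^4$ the relative
violation stays below $10^{-3}$ in all shipped scenarios (it peaks around
$7\times10^{-4}$ at the deepest lateral-ramp steps); the monotone
dependence on $K_V$ is a test.

### Numerical choices

* **Minimization.** Quasistatic equilibria are local minima of $W$ found by
  L-BFGS-B on all vertex coordinates with the analytic gradient, converged
  to a maximum per-vertex force norm below `tol` ($10^{-6}$ by default).
  Because the total energy is $O(10^3)$ while energy decrements near the
  minimum fall below the double-precision floor, line-search minimizers
  stall around force norms of $10^{-5}$; a Barzilai–Borwein gradient polish
  (gradient-only, no energy comparisons) then closes the gap to the force
  criterion. Both stages are deterministic, so runs are reproducible given
  the configuration.
* **Periodic images.** Integer lattice shifts per (face, vertex) incidence
  are frozen at build time from the reference flat packing. Topology is
  fixed (no neighbour exchanges, divisions or extrusions — folds form by
  shape change alone), and cells are far smaller than the half-box, so the
  frozen images keep $W$ exactly smooth across the boundary.
* **Collapse regularization.** Deep folds drive some apical junctions
  toward zero length (the crease line); with fixed topology the terms
  $\Lambda\lvert L\rvert$ and the triangle areas are non-differentiable
  there, and no smooth equilibrium would exist. Edge lengths and (twice-)
  triangle areas therefore enter $W$ as $\sqrt{x^2 + \varepsilon^2}$ with
  $\varepsilon = 5\times10^{-4}$ (`smooth_eps`): collapsed elements pin
  smoothly at the $\varepsilon$ scale while healthy elements (sizes
  $\gtrsim 0.3$) are perturbed only at $O(\varepsilon^2/x) \sim 10^{-6}$,
  far below every tolerance used.
* **Tie-breaks and degenerate inputs.** Cross-section planes that would
  pass exactly through a vertex are nudged by $10^{-9}$ box lengths; the
  cross-correlation argmin breaks ties toward the smallest lag magnitude;
  degenerate cycles (repeated vertices) and open cell surfaces are
  rejected with typed errors.

## The two folding mechanisms

Fold formation is simulated as a quasistatic ramp: a centred stripe of
`pre_fold` cells (2 rows by default; 4 available, matching the width of
the ECM-dilution stripe seen under the hinge fold) has its parameters
rescaled in 40 uniform steps, re-relaxing from the previous equilibrium at
each step (warm starting defines the quasistatic branch). The ramp
magnitude is the analog of the time axis; the model reproduces equilibrium
shapes, not folding dynamics.

* `basal_decrease`: $T_b, \Lambda_b \to (1+\delta_b)\,T_b, \Lambda_b$ with
  $\delta_b \le 0$, down to $\delta_b = -0.8$ by default — motivated by the
  ~70% basal recoil reduction measured in pre-fold cells of the
  hinge–hinge fold.
* `lateral_increase`: $T_l \to (1+\delta_l) T_l$ up to $\delta_l = +1$
  (hinge–pouch-fold mechanism, driven by lateral F-actin accumulation).
* `apical_increase`: the control; raising apical tension of the stripe
  does not appreciably fold the columnar tissue.

Both mechanisms produce folds with a pronounced apical indentation and
small basal deformation; the basal mechanism produces a much larger basal
cross-sectional length of the fold cells at matched indentation, and a
basal:apical tension ratio of 1 folds much less than the baseline ratio 4.
These four properties are asserted at the study scale (10×10 cells,
40 steps) in the acceptance tests.

Replicates: the reference quantification averages several simulations. What
distinguishes replicates is not stated beyond the packing, so `run_ramp()`
exposes a seeded vertex perturbation (amplitude 0.01, re-relaxed at
$\delta = 0$) as the replicate-to-replicate variation, and `glance()` on a
ramp reports mean ± s.e.m. across replicates.

## In-silico laser ablation

`ablate_element()` sets the tension of one element (apical or basal
junctional edge, or lateral face) to zero; `simulate_recoil()` integrates
the overdamped dynamics $\dot x = F/\gamma$ (explicit Euler,
$\Delta t = 10^{-5}$, stability checked by a step-halving test) from
the pre-ablation equilibrium and records the two bounding vertices —
for a lateral face, the midpoints of its apical and basal edges, so the
separation is the apical–basal extent of the released interface.
`recoil_velocity()` implements the first-frame estimator: separation
increase from the last pre-ablation sample to the first post-ablation
sample, divided by the window.

Only recoil *ratios* are compared with experiments, so the drag
coefficient and the reduced-time frame interval cancel as long as compared
elements use the same window; the frame interval is fixed at 0.01 reduced
time units, within the linear recoil regime (displacement ≈ 3% of an edge
length). The estimator applies the tracked-vertex formula literally, with
no correction for edge length or local geometry, since none is described
for the experimental estimate either.

## Fold-shape quantification

`extract_cross_section()` cuts the mesh with a plane perpendicular to the
fold and emits per-cell 2D segments; `measure_fold_geometry()` computes the
standard readout: apical indentation $d_a$, signed basal deformation $d_b$,
mean apical/basal cross-sectional lengths $l_a, l_b$ of the fold-centre
cells, and the neighbour tissue height $h_{\mathrm{tissue}}$ used to
normalize everything. Design choices that were genuinely open:

* The "apical plane of neighbouring cells" is a least-squares line through
  the apical segment endpoints of cells **at least two rows away** from the
  stripe (cells immediately adjacent are labelled `near` and excluded),
  mirroring the use of cells outside the fold in the tracked data.
* $d_b$ sign convention (ours, documented): positive = basal surface moves
  away from the apical side (outward bulge, hinge–hinge-like); negative =
  basal indentation (hinge–pouch-like). The two folds' basal deformations
  point in opposite directions, which this signed readout captures.

The same function accepts tracked cross-section tables from CSV
(`read_section_csv()`), so experimental trackings are analysed identically.

## Intensity/height cross-correlation

For paired per-cell series of lateral F-actin intensity $a_l(t)$ and cell
height $h(t)$, the function `actin_height_xcorr()` computes relative rates
$(1/x)\,dx/dt$ by central differences (endpoints dropped) and the plain
product-mean cross-correlation
$C(\tau) = \langle g_a(t)\, g_h(t+\tau) \rangle$, per cell and then
averaged across cells with equal weight. Conventions the source did not
pin down — derivative estimator, per-cell-then-average order — are chosen
once, recorded in the result's metadata, and a Pearson-normalised variant
and a linear log-detrend are available behind flags. The correlation is
deliberately not normalised by default because the target statistic is a
plain average of the product; it is scale free in both inputs regardless
(relative rates), which is what makes arbitrary fluorescence units usable.
`xcorr_null_bound()` gives a Bartlett-type bound under the independence
null, with an autocorrelation correction for the serial dependence that
central differencing introduces.

## What the synthetic generators emulate — and what they do not

The pixel-level steps of the original workflow (imaging, denoising,
segmentation, manual tracking) are out of scope; generators start at the
*tracked-table* level and reproduce the statistical structure each
estimator consumes:

* `gen_wedge_cross_section()` — piecewise-linear fold cross-sections
  realising exact $(d_a, d_b, l_a, l_b, h_{\mathrm{tissue}})$, with
  optional Gaussian tracking jitter.
* `gen_recoil_track()` — linear-recoil two-vertex tracks with positional
  noise and one pre-ablation frame.
* `gen_coupled_timeseries()` — log-intensity as a mean-reverting
  (Ornstein–Uhlenbeck) pulsatile process (correlation time 40 s, log-s.d.
  0.15, 10 s sampling over 600 s — the cadence and record length of
  lateral-surface imaging), with log-height driven by the delayed
  (22 s), negatively coupled intensity plus independent OU noise and an
  optional slow trend.
* `gen_intensity_table()` — per-cell intensities with a fold/neighbour
  contrast (0.8 mimics the ~20% collagen reporter reduction under the
  fold).

Every generator is a pure function of its arguments including the seed,
and every generator round-trips through its analysis stage exactly
(noise-free) or within two standard errors over seeded ensembles. Passing
these tests shows the *estimators* are correct and unbiased under the
generators' noise model — Gaussian, stationary, uncorrelated across cells.
It does not show robustness to what real trackings add: heteroscedastic
and autocorrelated tracking errors, missed frames, segmentation failures,
photobleaching trends in intensities. Real-data users should treat the
detrend and normalisation flags as sensitivity analyses, not defaults.

## Problem sizes

The shipped scenarios and acceptance checks use a 10×10-cell tissue with
40 ramp steps — folds there span the stripe plus a few neighbour rows and
the readouts are well converged with respect to tissue size, while a full
ramp relaxes in about a minute. Unit tests use 4×4 to 6×8 tissues; the
statistical ensembles use 50–200 seeds, sized so that two standard errors
resolve the biases being tested.

## Known limitations

* No fold dynamics: equilibrium shapes only, with the ramp magnitude as a
  pseudo-time.
* Fixed topology: no cell rearrangement, division or extrusion; collapsing
  junctions pin at the regularization scale instead of exchanging
  neighbours.
* Flat-sheet geometry: no curved disc, lumen pressure, or peripodial layer.
* Passive mechanics: tensions change only through the imposed ramps; there
  are no active fluctuating stresses or actomyosin turnover, so the
  pulsatile dynamics that motivate the lateral mechanism live in the
  synthetic generators, not in the mechanical model.
* The ECM spring anchoring (vertex-wise, zero rest length, full 3D
  displacement penalised) is the stated reading of the model sketch;
  alternatives (plane anchoring, normal-only penalty) would change the
  basal boundary condition and are not implemented.
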