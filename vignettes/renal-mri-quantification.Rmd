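---
title: "Quantitative multi-parametric renal MRI: models, phantom and reproducibility statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative multi-parametric renal MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(renalqmap)
```

# Scope

`renalqmap` implements a desk-scale model of a multi-parametric renal MRI
analysis workflow: voxel-wise quantitative mapping (T1 from MOLLI, ADC
from multi-b DWI, perfusion from pCASL), contour-based kidney volumetry,
a six-region renal ROI taxonomy with summary statistics, and
interobserver reproducibility statistics (ICC, CoV, Bland–Altman). Since
no patient images ship with the package, a synthetic kidney phantom with
known ground truth replaces the scanner: every downstream stage is
exercised and validated against values that are known by construction.

This vignette is the package's own account of the models, the default
parameter choices, the numerical decisions, and what the phantom does
and does not establish about real data.

# Signal models

## T1 mapping (MOLLI)

Signed inversion-recovery signal is modelled per voxel as

$$S(\mathrm{TI}) = A - B\,e^{-\mathrm{TI}/T_1^*},$$

with the Look-Locker correction $T_1 = T_1^*\,(B/A - 1)$. Phase-sensitive
reconstruction preserves signal polarity, so the phantom generates signed
data and the fitter consumes it directly; magnitude (Rician) data is
available as a simulation option but is not the default. Clinical MOLLI
products implement proprietary fitting; the three-parameter model used
here is the standard published formulation, and recovered values on real
data need not match a specific vendor pipeline.

The default inversion-time schedule is the 14-TI scheme
(180, 260, 730, 810, ..., 5680 ms; 550 ms increments after the two
initial delays). The phantom's inversion efficiency $\beta$ defaults to 1
(so $B = 2A$ and $T_1^* = T_1$), making ground truth map directly onto
the recovered parameter; it is configurable for robustness studies.

**Fitting.** A variable-projection scan over $T_1^*$ (80 log-spaced
candidates in 50–10000 ms, each with a closed-form linear solve for
$A, B$) initialises every voxel; a vectorised Levenberg–Marquardt
refinement then iterates until the SSE change falls below $10^{-12}$
(at most 200 iterations), under the positivity constraints
$A, B, T_1^* > 0$. Voxels that are all-zero, fail positivity, or do not
converge are flagged in the map's `flags` array and set non-finite —
never raised as errors, since single bad voxels are routine in real maps.

## ADC mapping (DWI)

Mono-exponential decay $S(b) = S_0\,e^{-b\,\mathrm{ADC}}$ over the
ten-b-value schedule (0–1000 s/mm²; $b = 0$ required as the $S_0$
anchor). Log-linear regression on the positive signals initialises
$(S_0, \mathrm{ADC})$; the same LM refinement polishes the fit with
$S_0 > 0$, $\mathrm{ADC} \ge 0$. A voxel pinned at the
$\mathrm{ADC} = 0$ boundary (constant signal) keeps the value 0 and is
flagged. Maps are stored in mm²/s; the conventional
$\times 10^{-6}$ mm²/s reporting scale is applied only at the reporting
layer (as in the pipeline's tidy outputs).

## Perfusion (pCASL)

The single-compartment kinetic model

$$\Delta M = f\,\frac{2 M_0}{\lambda}\,T_1'\,\alpha\,
  e^{-\Delta t/T_{1,\mathrm{blood}}}\,
  e^{-(t-\tau-\Delta t)/T_1'}\,\bigl(1 - e^{-\tau/T_1'}\bigr)$$

links perfusion $f$ to the label/control difference $\Delta M$, with
defaults $t = 3000$ ms, $\tau = 1500$ ms, $\Delta t = 750$ ms,
$\alpha = 0.98$, $\lambda = 0.9$ ml/g,
$T_{1,\mathrm{blood}} = T_1' = 1250$ ms. $f$ is handled internally in
ml g⁻¹ ms⁻¹ and reported in ml/100 g/min. The map inversion is the
closed-form rearrangement; negative voxel values (expected under noise)
are preserved in the map, included in ROI statistics, and their fraction
is reported as a QC attribute.

**A note on $\lambda$'s units.** The partition coefficient is sometimes
loosely written as "0.9 ml/100 g"; the conventional value is 0.9 ml/g,
and using the former verbatim would shift perfusion estimates by two
orders of magnitude out of the physiological range (renal cortical
perfusion of roughly 100–400 ml/100 g/min). The package computes with
0.9 ml/g; the constant is configurable in `asl_constants()`.

The model assumes a single well-mixed compartment, a fixed blood/tissue
T1, and complete label arrival after $\Delta t$; multi-compartment
kinetics and measured-T1-driven quantification are out of scope.

# The synthetic kidney phantom

`make_kidney_labelmap()` builds a single coronal kidney on a
(slice, row, column) grid: an ellipsoidal organ whose outer shell is
cortex, with wedge-shaped medullary pyramids separated by cortical
columns in the interior, and an interior fluid-filled renal pelvis. The
defaults — a 12 × 64 × 64 grid at (4, 1.5, 1.5) mm — give an organ of
roughly 55 ml, at the lower end of the human range, chosen so full
simulations stay fast while every geometric feature (shell topology,
pelvic exclusion, polar thirds) is resolved. Seed-dependent jitter of the
centre, semi-axes and pyramid phase makes subjects distinct; the
geometry guarantees kidney-free slices at both stack ends so "first and
last slices containing renal tissue" is always well defined.

Default tissue values span the ranges reported for human kidney at 3 T:

| compartment | T1 (ms) | ADC (mm²/s) | perfusion (ml/100 g/min) | M0 |
|---|---|---|---|---|
| cortex  | 1630 | 1.68e-3 | 221 | 1000 |
| medulla | 1976 | 1.67e-3 | 96  | 1000 |
| pelvis  | 3200 | 3.0e-3  | 1   | 1000 |

with medullary T1 above cortical and cortical perfusion above medullary,
the directions seen in vivo. The pipeline draws per-subject values
around these means (e.g. cortical T1 SD 100 ms) to emulate
between-subject spread.

**Noise calibration.** Gaussian noise of configurable SD is added to the
signed data (Rician optionally, for magnitude-mode simulations). The
defaults — 50 signal units for MOLLI, 25 for DWI and 2.5 for ASL, against
a baseline of 1000 — are calibrated so that the within-ROI SD of a small
homogeneous cortical ROI matches the spread reported for representative
cortex in patient data (about 3% of the mean for T1, 4% for ADC and 16%
for pCASL). This is the one place where the phantom is tuned to an
observed, published property of real maps rather than to first
principles: phantom compartments are internally homogeneous, so voxel
noise must stand in for everything (true noise, perfusion heterogeneity,
partial volume) that broadens real within-ROI histograms.

**What the phantom does not emulate:** respiratory motion and
registration error, partial-volume gradients at compartment borders,
within-compartment physiological heterogeneity, susceptibility/EPI
distortion in DWI, transit-time dispersion in ASL, and multi-coil noise
correlation. Consequently, passing round-trip tests establishes the
correctness of the estimators and the pipeline plumbing — not the
clinical accuracy of the acquisition models on patient data.

## Simulated observers

`perturb_contours()` models a second human observer: each contour vertex
moves along its local outward normal by `bias_mm` plus zero-mean
Gaussian jitter. The jitter is spatially correlated along the ring (a
five-vertex smoothing kernel, rescaled to keep the requested marginal
SD) because a human redraw deviates smoothly, not voxel-by-voxel;
uncorrelated vertex noise would both exaggerate area variance and
routinely self-intersect. Draws that still self-intersect are redrawn
deterministically. Hole rings move in the opposite sense, so positive
bias means systematic over-contouring of the region. With zero jitter
and zero bias the observer is the identity, and the pipeline then also
reuses the same representative-cortex placement, so a zero-variability
configuration yields ICC = 1 and CoV = 0 exactly.

No published estimate of contour-level observer variability was
available to anchor the jitter magnitude; the default of 0.5 mm
(one-third of an in-plane voxel) is the package's own choice and should
be treated as a what-if dial, not a measured quantity.

# Volumetry

Volumes integrate net polygon area (outer rings minus holes, shoelace
formula) times slice spacing. Two protocols are implemented: contours on
**every slice**, and contours on the first, last and every **alternate**
slice with linear interpolation for the gaps. Interpolation acts on the
scalar cross-sectional *area*, not on contour shape: with only "linear
interpolation" to go on, area interpolation is the simplest faithful
reading, and it makes the two protocols provably identical whenever the
area profile is affine in slice index (a property the tests assert to
machine precision). For a dome-shaped profile the chord lies under the
curve, so the alternate-slice volume is systematically slightly smaller —
the direction observed when both protocols are applied to the same
kidneys. End slices must be contoured; the implementation never
extrapolates. The renal pelvis is excluded from the whole-kidney region;
in the phantom it is interior, so exclusion surfaces as hole rings that
subtract from the enclosed area.

# ROI taxonomy and statistics

Six ROI kinds are defined on a single analysis slice (in the pipeline:
the slice of maximal kidney area, mirroring single-slice clinical
analysis): whole kidney excluding pelvis (WK), cortex (Cx), a circular
user-defined representative cortex (repCx, default radius 4 mm, placed
at a seeded random location whose full disc fits inside cortex),
superior and inferior polar cortex (supCx/infCx: cortex within the outer
thirds of the kidney's in-slice bounding box — no standard geometric
definition of "pole" exists, so the bounding-box thirds rule is the
package's own), and a connected medullary region (Med, the largest
connected component).

Rasterisation uses the voxel-centre even-odd rule with subtractive
holes. Within-ROI SD uses the population ($n$) divisor by default,
mirroring the convention of clinical ROI software, and is configurable
to $n-1$. The `sd_fraction` (SD as a fraction of the mean) is the
package's diagnostic for the heterogeneity of a region: on any
two-compartment kidney the WK value mixes cortical and medullary
distributions, so its spread exceeds that of any single-compartment ROI
even in noiseless data — the quantitative argument for preferring
cortical ROIs over whole-kidney means.

# Reproducibility statistics

- **ICC(2,k)** (two-way random effects, average measures, agreement):
  computed from the explicit mean squares
  $\mathrm{ICC} = (MS_R - MS_E)/(MS_R + (MS_C - MS_E)/n)$, with the mean
  squares retained in the result for audit. Negative estimates are
  reported as computed. The test suite cross-checks against a
  double-loop ANOVA decomposition, `stats::aov` mean squares, and a
  frozen value from an independent published implementation.
- **CoV**: per subject, SD of the rater values over their mean
  ($n-1$ divisor; for two raters $|d|/\sqrt{2}$), averaged across
  subjects and reported in percent. Whether to average per-subject CoVs
  or pool them as an RMS is a convention choice that published reports
  rarely state; the default is the per-subject mean, with RMS pooling
  available (`pooling = "rms"`). CoV values computed from summary tables
  are therefore not exactly recomputable without the raw data.
- **Bland–Altman**: bias = mean difference (observer A − B, fixed by
  input order), limits of agreement at ±1.96 SD.
- t-tests, Pearson correlation and one-way ANOVA are delegated to
  `stats`; the 0.05 significance convention is applied only when
  reporting.

# The end-to-end pipeline

`run_pipeline()` chains every stage for `n_subjects` phantoms and two
simulated observers and returns tidy tables plus reproducibility
reports; all randomness derives from the single config seed via a
recorded manifest, and repeated runs are byte-identical. Default problem
sizes (8 subjects for exploration, 20 in the acceptance script, the
12 × 64 × 64 grid, map fitting restricted to the analysis slice) were
chosen so a full study simulates in well under a minute on one core
while leaving thousands of voxels per fit.

Two behaviours of the simulated study are worth stating because they
reproduce the qualitative structure of interobserver studies on real
kidneys: (i) whole-kidney means are extremely robust to contour jitter
(thousands of voxels average out both noise and boundary changes), so
CoV(WK) is small; (ii) a small repCx disc re-placed independently by
each observer samples different noisy voxels, so CoV(repCx) exceeds
CoV(WK) even though repCx sits in homogeneous cortex. Large-ROI
reproducibility and small-ROI representativeness pull in opposite
directions — the core trade-off the reproducibility statistics are
designed to expose.

# Numerical choices and degenerate inputs

- LM refinement: SSE-change tolerance $10^{-12}$, max 200 iterations,
  multiplicative damping (×10 on rejection, ÷3 on acceptance); a voxel
  whose damping saturates is reported at its best-found parameters.
- Grid initialisation brackets: $T_1^* \in [50, 10^4]$ ms (80 log-spaced
  points); ADC capped at 0.05 mm²/s.
- Contour extraction traces the 0.5 iso-level between voxel centres
  (marching squares), so rasterising an extracted contour reproduces the
  source mask exactly for non-degenerate shapes; masks thinner than one
  voxel are not guaranteed to survive the round trip.
- Tie-breaks: the analysis slice is the first slice attaining the
  maximal kidney area; the Med ROI takes the first-labelled largest
  component on ties.
- Degenerate inputs error early with messages naming the offending
  slice, subject or field: missing intermediate slices (every-slice
  protocol), gaps of more than one slice (alternate protocol), schedule
  / frame-count mismatches, zero medullary means, zero total variance in
  ICC, sub-minimal grids.

# Known limitations

- The phantom's geometric realism is deliberately minimal (ellipsoid,
  wedge pyramids, interior pelvis); it validates algorithms, not
  segmentation difficulty.
- Single kidney per subject; native-vs-transplant differences enter only
  through tissue parameter priors, not geometry.
- The T1 fitter assumes signed data; feeding magnitude data without
  polarity restoration will bias short-TI fits.
- ASL quantification uses the fixed-T1 model above; errors in the
  assumed $T_1'$ propagate multiplicatively into $f$.
- Observer simulation covers contour geometry only — it does not model
  disagreement about slice selection or windowing.
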