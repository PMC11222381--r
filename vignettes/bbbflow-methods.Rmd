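---
title: "Methods: BBB leakage and pulsatility estimation in bbbflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: BBB leakage and pulsatility estimation in bbbflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bbbflow)
```

# Scope

bbbflow implements three connected layers: (i) estimation of blood–brain
barrier leakage (PS) and fractional plasma volume (v~p~) from DCE-MRI via
variable-flip-angle T1 mapping, a sinus-derived vascular input function and
the Patlak model; (ii) cerebral arterial waveform, pulsatility-index and
total-flow estimation from 4D flow volumes via centerline processing; and
(iii) the cohort statistics that relate these quantities to age and
cognition. A digital phantom generates every input with exact ground truth,
which is what the test suite and the acceptance script exercise.

# The DCE model chain and its assumptions

**SPGR forward model.** All signal synthesis and inversion uses the spoiled
gradient-echo steady state
$S = M_0 \sin(b_1\alpha)\,(1-E_1)/(1-\cos(b_1\alpha)E_1)$ with
$E_1 = e^{-TR/T_1}$. Perfect spoiling and a steady state at every dynamic
frame are assumed; TR is in ms (default 4.5), T1 in seconds.

**VFA T1 fit.** The standard linearization ($y = S/\sin\alpha_{\rm eff}$ on
$x = S/\tan\alpha_{\rm eff}$, $\alpha_{\rm eff} = b_1\alpha$) is solved in
closed form per voxel — exact for two angles, least squares for three or
more. It is deterministic and, on noiseless input, an identity: the test
suite verifies recovery to 1e-9 relative error over 1000 random
(T1, M0, B1) states with B1 in [0.7, 1.3]. Voxels whose slope leaves (0, 1),
whose design is degenerate, or whose signal does not vary with flip angle
are flagged invalid and never imputed; region averages use valid voxels
only.

**Signal to concentration.** The dynamic M0 is estimated from the mean of
`nBaselineFrames` pre-injection frames (default 3: with 17.5 s frames and an
injection starting after about a minute, three frames are safely
pre-contrast). Each frame is then inverted analytically — no iterative
fitting — which is exact under the fast-water-exchange assumption, and
$C(t) = (R_1(t)-R_{10})/r_1$ with $r_1 = 3.5$ L·mmol⁻¹·s⁻¹. Negative
concentrations are preserved (they are informative noise) and only counted
in QC.

**VIF extraction.** Correlation is computed on raw signal curves, not
concentrations, and the mask threshold defaults to R = 0.99. The mask is
thinned to a centerline (see below) and the 25 voxels averaged are chosen
contiguously starting at the centerline point nearest the seed, extending
toward the longer limb. The placement rule is a package decision — any
contiguous window is defensible; contiguity minimizes partial-volume
heterogeneity and the rule is deterministic. The plasma conversion divides
by (1 − HCT) with HCT = 0.45 assumed for all subjects.

**Patlak fit.** Two-regressor, no-intercept OLS of C~tissue~ on
[∫C~VIF~ dt (minutes), C~VIF~]. There is no intercept because the model has
none, and no non-negativity constraint because unconstrained distributions
are the objective — thresholding would bias cohort means. The integral is a
cumulative trapezoid on the frame time stamps. Scaling checks
(VIF × k ⇒ PS, v~p~ ÷ k; C~tissue~ + a·C~VIF~ ⇒ v~p~ + a) hold to machine
precision. With simulated reversible efflux the fit underestimates PS — a
documented model-misspecification property, not an accuracy claim.

**Discrete-time forward model.** The phantom's tissue curves are generated
with the *same* trapezoidal quadrature on the frame grid that the estimator
uses. This makes the forward–inverse chain an exact round trip (≤1e-6
relative error end-to-end, in practice ~1e-13), which is the correct
fixture semantics: quadrature error is a property of the 17.5 s sampling,
not of the estimator, and burying it in the generator would turn every
round-trip test into a test of the frame rate.

# Centerline processing

**Thinning.** No installed R package offers 3D topological thinning, so it
is implemented directly: sequential removal of simple points under (26, 6)
connectivity, where simplicity requires exactly one 26-connected foreground
component in the 26-neighborhood and exactly one 6-connected background
component in the 18-neighborhood touching a face. Three safeguards keep the
skeleton geometrically sane: voxels are visited in increasing
distance-from-background order (centeredness); each cycle is split into six
directional subiterations further divided into eight parity subfields, so
removals within a pass are never adjacent — equivalent to parallel thinning,
which prevents elongated structures from being eaten end-to-end; and curve
endpoints (single-neighbor voxels) are protected. Leaf twigs no longer than
the tube radius are pruned as erosion artifacts, and pruning/thinning
alternate to joint convergence.

**End reconstruction.** Thinning erodes roughly one radius from each flat
tube end. For the VIF centerline the longest path is therefore extended
along its end tangents while still inside the mask, recovering the nominal
length (a 20-voxel tube of radius 3 yields a 20-voxel centerline).

**Branch decomposition.** The skeleton graph (26-adjacency) is split at
junction voxels (degree ≥ 3); each remaining component is ordered into a
path and terminated by its adjacent junction voxels.

# Cross-section flow and the lumen threshold

At a centerline voxel the cross-section is the one-voxel slab perpendicular
to the tangent (|projection| ≤ half a voxel) — velocities are used where
they live instead of being interpolated. The tangent is the principal
direction of the voxel and ±3 path neighbors (±2 for distal branches).
Flow is Σ (v·t̂)·A per voxel with A = voxel volume / slab thickness.

Two local CD thresholds are used deliberately. The **flow** lumen uses 15%
of the local CD peak: with a parabolic velocity profile and CD proportional
to time-averaged speed, a cut at fraction c of the peak captures exactly
1 − c² of the flux, so the FWHM cut (c = 0.5) would lose 25% of the flow
while c = 0.15 loses 2.2%. The **diameter** estimate keeps the FWHM cut
(c = 0.5), the standard PC-MRI caliper, as the equivalent-circle diameter of
the lumen area at the branch's median section. Lumen voxels must be
connected to the centerline point, which guards against neighboring
vessels entering the integral.

Waveform post-processing: periodic cubic-spline interpolation from 20 to
2000 frames per cycle (the cardiac cycle is cyclic, so the periodic
boundary is the only defensible one); PI = (max − min)/mean of the
interpolated waveform; the artery cluster in K-means is the one with the
higher mean PI (deterministic, physiologically motivated); K-means is
initialized from the extreme-PI waveforms so no RNG is consumed; with only
two branches the assignment to the two centers is the identity. The distal
composite waveform is the frame-wise median of mean-normalized section
waveforms, re-normalized to mean exactly 1.

# The phantom: what it emulates, and what it does not

Geometry is analytic — spheres for tissue regions, straight tubes for
vessels — because exact ground truth is the point; no anatomical realism is
attempted. The DCE phantom reproduces the acquisition constants (flip
angles 2/8/12°, TR 4.5 ms, 60 frames at 17.5 s, injection starting at 60 s
lasting 60 s), region-wise PS in [0.3, 1.0]·10⁻³ min⁻¹ and v~p~ in
[0.7, 1.9]%, a smooth B1 deviation field (default amplitude 10%), and
Rician noise realized as Gaussian noise on two quadrature channels. The
blood VIF is a unit-area linear-ramp bolus convolved with a bi-exponential
washout (amplitudes 3.0/1.5 mM, rates 0.35/0.015 min⁻¹), giving the low,
rounded peak of a slow one-minute injection without modelling dispersion.
The flow phantom carries Poiseuille profiles scaled so the analytic
cross-section integral equals the prescribed waveform; venc only bounds
amplitudes (no phase wrapping is simulated). The cohort generator uses a
one-factor PS model whose loadings can be tuned to any first-PC share
(default 0.17 vs noise 0.10, population share 0.76), MoCA slope −2.9 per
10⁻³ min⁻¹, and pulsatility/age independent of PS.

Passing tests on this phantom therefore demonstrate correctness of the
estimators under the stated models — they do not demonstrate robustness to
motion, dispersion, partial-volume mixtures at anatomical boundaries,
imperfect spoiling, slab-profile errors, or segmentation error, none of
which the phantom contains. The DCE noise level is a free parameter
(default 0 for round-trip fixtures; SNR ≈ 30–50 in stochastic tests) since
no canonical value exists.

# Numerical and design choices

- Units: R1 in s⁻¹, concentration in mM, time in seconds everywhere except
  inside the Patlak integral (minutes), so PS is in min⁻¹ unmodified;
  tables report PS·10³ and v~p~ in percent with units in the column names.
- All generators draw from one explicit seed argument through a local RNG
  scope; nothing touches the global random state.
- The Patlak design matrix is solved by QR with a rank check; an all-zero
  VIF or fewer than three usable frames is an error, never an NA.
- ICC is the two-way random, absolute-agreement, single-measure form
  ICC(2,1); the form is configurable in principle but this default is what
  interrater agreement of a continuous measurement calls for. Exact
  agreement returns 1 even for a degenerate constant matrix.
- Peak-exclusion window: frames overlapping injection start to injection
  end plus one frame, configurable.
- Aggregates (cortex, white matter, basal ganglia, whole brain) are
  unweighted means over constituent regional estimates.
- Sex enters residualization as a 0/1 indicator; no multiple-comparison
  correction is applied by default.
- PCA for shared variance runs on the correlation matrix because regions
  differ in scale.
- Background velocity correction fits the spatial polynomial (default
  degree 2, coordinates normalized to [−1, 1] for conditioning) to
  time-averaged velocities over static voxels only, then subtracts the
  fitted field everywhere.

Problem sizes in the shipped tests and acceptance script — a 32³ phantom
with 60 frames, a 48³ flow phantom with 20 cardiac frames, 1000-replicate
Monte-Carlo runs, 10⁴-replicate calibration checks — were chosen as the
smallest sizes at which the targeted properties are stable; the whole suite
runs in well under a minute.

# Known limitations

Real-data co-registration, brain segmentation and DICOM handling are out of
scope; volumes are assumed aligned (a shape/spacing consistency check
guards this). The thinning-based centerline can wobble by a voxel near tube
ends, which the 15-section averaging absorbs. The lumen threshold model
assumes CD ∝ speed with a dark background; bright static tissue would
require an explicit background estimate. Distal arteries near one voxel in
diameter cannot be voxelized faithfully at the phantom's resolution, so
diameter-threshold behavior is tested at the classification layer rather
than through sub-voxel tubes. PS from the Patlak model is a
permeability–surface-area product, not a pure permeability; interpreting
cohort-level differences still requires the usual care.
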