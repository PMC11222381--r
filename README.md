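# bbbflow

Quantifies subtle blood–brain barrier (BBB) leakage and cerebral arterial
pulsatility from MRI, and the statistics that relate them to cognition at
cohort level. The package is aimed at researchers analysing dynamic
contrast-enhanced (DCE) MRI and 4D flow MRI of the aging brain, and at anyone
who wants a fully testable reference implementation of this pipeline: every
stage can be exercised on a built-in digital phantom with exact ground truth,
so no patient data are required.

## What it computes

**BBB leakage (DCE-MRI).** Baseline T1 maps come from the variable-flip-angle
(VFA) method with B1 correction: for spoiled-gradient-echo signals
S(α) at flip angles α ∈ {2°, 8°, 12°} (TR 4.5 ms), the linearization
y = S/sin(b₁α), x = S/tan(b₁α) has slope E₁ = exp(−TR/T₁). Dynamic signals
are inverted analytically to R₁(t), and gadolinium concentration follows

    C(t) = (R₁(t) − R₁₀) / r₁ ,   r₁ = 3.5 L·mmol⁻¹·s⁻¹.

The vascular input function is extracted from the superior sagittal sinus:
a seed voxel, a cross-correlation mask at R ≥ 0.99, topological thinning to a
centerline, averaging of 25 centerline voxels, and plasma conversion
C_VIF = C_b/(1 − HCT) with HCT = 0.45. The Patlak model

    C_tissue(t) = PS ∫₀ᵗ C_VIF(τ) dτ + v_p · C_VIF(t)

is solved for the permeability–surface area product PS (min⁻¹) and the
fractional plasma volume v_p by two-regressor, no-intercept least squares —
unconstrained, with no thresholding of extreme values.

**Pulsatility (4D flow MRI).** The complex-difference angiogram is
thresholded and thinned to a one-voxel centerline tree, subdivided at
junctions. Per centerline voxel, a cross-section perpendicular to the local
tangent is segmented by a local CD threshold and the tangential velocity is
integrated to a flow waveform (ml/min over 20 cardiac frames). Waveforms are
interpolated to 2000 frames with periodic cubic splines; the pulsatility
index is PI = (max − min)/mean. K-means (K = 2) on mean-normalized
branch waveforms separates arteries from veins, a 1.25 mm diameter threshold
separates large from distal arteries, and total cerebral blood flow is the
summed mean inflow of both internal carotids and the basilar artery.

**Cohort statistics.** Descriptives with skewness/excess-kurtosis normality
indices, Pearson correlation, linear regression with t-based 95% CIs,
covariate adjustment by residualization, shared-variance PCA on the
correlation matrix, and ICC(2,1) for interrater agreement.

**Phantom.** Analytic spheres/tubes with exact per-region ground truth,
forward Patlak kinetics, SPGR signal synthesis, Rician noise, pulsatile
Poiseuille tube flow, and synthetic cohorts with a one-factor between-region
PS structure and a linear PS→MoCA effect.

## Worked example

```r
library(bbbflow)

res <- runDCE(list(seed = 2))
res$table
#>          region PS_1e.3_per_min vp_percent n_voxels is_aggregate
#> 1      thalamus       0.4000000   0.800000      123        FALSE
#> 2       caudate       0.6000000   1.200000      123        FALSE
#> 3       putamen       0.9000000   1.800000      123        FALSE
#> 4 basal_ganglia       0.7500000   1.500000      246         TRUE
#> 5   whole_brain       0.6333333   1.266667      369         TRUE
```

The noiseless phantom's true PS values are 0.4, 0.6 and 0.9 (·10⁻³ min⁻¹)
and its true v_p values 0.8, 1.2 and 1.8% — the table above recovers them to
numerical precision through the full chain (VFA T1 fit → signal inversion →
concentration → sinus VIF → Patlak). Aggregates are unweighted means over
the constituent regions.

```r
flow <- runFlow(list(seed = 3))
flow$table
#>    vessel       pi mean_flow_ml_min
#> 1   ICA-L 1.140051         214.4073
#> 2   ICA-R 1.140051         214.4073
#> 3      BA 1.140051         113.0511
#> 4 ICA-avg 1.140051         214.4073
#> 5  distal 0.990044               NA
#> 6    tCBF       NA         541.8656
```

The tube phantom generates ICA/BA waveforms with PI 1.14, a distal artery
with PI 0.99 and a total inflow of 556 ml/min; the pipeline recovers the
pulsatility indices to ±0.001 and tCBF within 2.6% (the small deficit is the
near-wall flow below the lumen threshold).

A command-line wrapper over these functions ships in
`inst/scripts/bbbflow.R` (phantom generation to NIfTI + JSON, pipeline runs,
`selftest`).

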