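---
title: "Plaque material models and revascularisation stress: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plaque material models and revascularisation stress: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plaqueMech)
```

## The scientific problem

Numerical simulations of endovascular intervention in the femoral arteries
frequently borrow material data measured on *aortic* plaque tissue, because
mechanical characterisations of *femoral* plaque are scarce. The two tissues
behave very differently: aortic fibrous-cap samples show the collagen
stiffening of near-healthy intima, while femoral plaques are heavily
calcified, fibrotic structures with a much softer, flatter response.
plaqueMech quantifies the consequence of that substitution on a common
modelling task — the revascularisation (balloon-opening) of a stenosed
femoral artery — by carrying both families of material models through an
identical simulation and comparing the stresses each predicts in the plaque.

The package covers three stages: constitutive model construction from
planar-shear test data, FTIR-based grading of plaque calcification (which
defines the femoral material groups), and a plane-strain inflation
simulation with failure assessment.

## Constitutive model

Plaque tissue is modelled as isotropic, incompressible and hyperelastic with
the third-order reduced-polynomial (Yeoh) strain energy function

$$\Psi(I_1) = \sum_{i=1}^{3} C_{i0}\,(I_1 - 3)^i ,$$

which depends only on the first invariant $I_1$ of the Cauchy–Green tensor.
This form suits uniaxial planar-shear data: with principal stretches
$(\lambda, 1, 1/\lambda)$, $I_1 = \lambda^2 + 1 + \lambda^{-2}$ and the
loading-direction Cauchy stress of an incompressible material is

$$\sigma = 2\,(\lambda^2 - \lambda^{-2})\,\frac{\partial\Psi}{\partial I_1}.$$

This stress expression is standard but easy to mis-derive, so the test suite
validates it against numeric differentiation of the strain energy along the
planar-shear path ($\sigma = \lambda\, d\hat\Psi/d\lambda$) rather than
trusting the algebra.

An isotropic model is a deliberate restriction: anisotropic fibre models
need multi-axial data and collagen architecture that uniaxial-to-failure
testing of small plaque samples cannot provide, and the femoral samples'
behaviour is dominated by heterogeneous calcified/fibrous tissue rather than
organised fibres.

**Stability.** Fitted coefficient sets are screened with a Drucker-type
criterion implemented as strict monotonicity of the planar-shear stress:
the analytic tangent $d\sigma/d\lambda$ must be positive on a dense grid
(default $10^4$ points) over the curve's stretch range. Monotonicity of the
fitted-mode response is used as the proxy because the precise criterion
enforced by the original Matlab fitting procedure is not recorded; for the
single-invariant Yeoh form in a single deformation mode the two notions
coincide in practice. The tangent is evaluated analytically, not by
differencing.

## Fitting

`fitYeoh()` minimises the sum of squared stress differences between the
model and the data — the same objective whether or not stability is
enforced. Technically the planar-shear stress is *linear* in
$(C_{10}, C_{20}, C_{30})$, but the fit still runs through bounded
Levenberg–Marquardt (`minpack.lm`) with a seeded 10-start multi-start so
that the stability constraint can be enforced by rejection-and-restart:
candidate minima with a non-monotone response over the data's stretch range
are discarded and the best stable candidate is kept. $C_{10}$ is bounded
below by $10^{-6}$ MPa to exclude zero-stiffness degeneracy; an all-zero
signal therefore returns $(10^{-6}, 0, 0)$ with essentially zero residual.
Fit quality is reported as $R^2$ in stress space (the natural space of the
objective).

**Identifiability caveat.** $C_{10}$ controls the small-strain slope. For
material groups whose response is dominated by the higher-order terms over a
short stretch range (the calcified aortic set has
$C_{10} = 1.41\times10^{-3}$ MPa against $C_{20} = 4.73$ MPa on
$\lambda \in [1, 1.19]$), $C_{10}$ contributes well under 1% of the stress
signal, and no fitting procedure can recover it reliably from noisy data.
Noisy-recovery tests therefore target the femoral groups, where $C_{10}$ is
the dominant coefficient; noiseless recovery is exact (to optimiser
tolerance) for all six groups.

**Group averaging.** A group's average curve is built by pooling all
samples' points and fitting one polynomial in $(\lambda - 1)$ constrained
through $(1, 0)$, then sampling it on a uniform grid truncated at the
group's mean ultimate failure stretch. The default degree is 5: a cubic —
the naive match to the Yeoh form's cubic-in-$I_1$ capacity — leaves
reconstruction errors up to $4\times10^{-2}$ MPa on the stiffer groups
because the planar-shear stress is not cubic in $(\lambda-1)$, while degree
5 reconstructs all six published group responses to better than
$3\times10^{-4}$ MPa. The degree is configurable.

## FTIR classification

Calcification is graded by the calcification-to-lipid peak-area ratio
(Ca:Li): the phosphate band area (1180–900 cm⁻¹) over the lipid area, which
is the CH₂ stretch band (2972–2845 cm⁻¹) plus the carbonyl ester band
around 1730 cm⁻¹. Design choices where the protocol is under-specified:

* **Ester band width** — 1750–1710 cm⁻¹ (typical carbonyl width),
  configurable. The ester peak is not always detectable; its
  baseline-corrected area is included whenever positive, which (with areas
  clipped at zero) means it is always added.
* **Baseline** — a local linear baseline joining the band endpoints is
  subtracted before integration, the minimal assumption consistent with
  instrument-software area tools. This makes areas exactly invariant to any
  global linear-in-wavenumber background.
* **Integration grid** — bands are resampled to a uniform grid at the 2 cm⁻¹
  acquisition resolution (or the native spacing when finer) and integrated
  by the trapezoidal rule; negative net areas are clipped at zero.
* **Interval boundaries** — the published class intervals are open on both
  sides, leaving boundary ratios unassigned; the package adopts the
  half-open convention $[{\rm lo}, {\rm hi})$, so 1.5 is "moderately" and
  2.0 is "heavily". Ratios $\le 1$ or $\ge 3$ are "unclassified".

## Inflation simulation

The reference geometry is a concentric two-layer ring: plaque from the
initial stenosed lumen radius $R_i$ to the healthy-lumen interface
$R_p$, wall from $R_p$ to $R_o$ (defaults: $R_i = 0.2975$,
$R_p = 2.975$, $R_o = 3.435$ mm). Revascularisation displaces the lumen
surface to the final-stenosis radius $r_i$ (default 2.6775 mm).

The original quarter-symmetric plane-strain model with symmetric boundary
conditions is mathematically axisymmetric, so the package solves the exact
1D radial reduction rather than meshing hundreds of thousands of plane
elements:

* **Kinematics.** Plane strain ($\lambda_z = 1$) plus exact
  incompressibility force $r(R) = \sqrt{R^2 + r_i^2 - R_i^2}$ — every
  sub-annulus conserves its area identically. Exact incompressibility is
  the natural treatment because the Yeoh form used has no volumetric term.
* **Equilibrium.** $d\sigma_{rr}/dr = (\sigma_{\theta\theta} -
  \sigma_{rr})/r$ is integrated inward from the traction-free outer
  surface by the cumulative trapezoidal rule, with
  $\sigma_{\theta\theta} - \sigma_{rr} = 2(\lambda_\theta^2 -
  \lambda_\theta^{-2})\,\partial\Psi/\partial I_1$ and
  $\sigma_{zz} = \sigma_{rr} + 2\,\partial\Psi/\partial I_1\,
  (1 - \lambda_\theta^{-2})$.
* **Grid.** 4000 nodes by default, geometrically clustered toward the lumen
  (clustering strength 8) where the hoop stretch — up to $r_i/R_i = 9$ for
  the default geometry — and its gradients are steepest; the plaque/wall
  interface node is inserted exactly. On this grid the central-difference
  equilibrium residual is below $10^{-6}$ of the peak hoop stress and the
  outer radial traction vanishes to $10^{-8}$ MPa (both asserted on every
  solve in the tests).
* **Extrapolation.** Opening a 90% stenosis stretches the inner plaque far
  beyond any tested regime; the strain energy function is evaluated along
  its predicted path, as in the original analysis. Non-monotone behaviour
  over the induced stretch range triggers a warning, not an error.

Two independent solvers guard the implementation in the test suite: the
classical closed-form solution for the incompressible neo-Hookean
plane-strain cylinder (agreement to $10^{-7}$ relative, asserted at
$10^{-3}$), and a displacement-driven finite-difference solver with penalty
incompressibility (500 nodes, penalty $2\times10^4$ times the largest
$C_{10}$, damped Newton on the tridiagonal Hessian) that agrees with the
semi-analytic hoop-stress profile to $\sim 2\times10^{-4}$ relative
(asserted at 1%) on a moderate-stretch two-layer instance.

### Undetermined conventions and their defaults

Three modelling choices are not recorded in the source analysis; each is a
configurable default, and `runStudy()` writes a sensitivity appendix over
all of them:

* **Stenosis-percentage reference.** The geometry table references stenosis
  percentages to the SFA diameter, but the model description references the
  90% stenosis to the luminal diameter. Default: `healthy_lumen`, because
  the SFA reading makes the final lumen (3.09 mm radius) exceed the healthy
  lumen interface (2.975 mm), which is inconsistent for a concentric plaque.
  Both conventions are implemented.
* **Wall material.** The healthy media/adventitia model is unspecified.
  Default: neo-Hookean with $C_{10} = 0.05$ MPa (soft-tissue shear-stiffness
  scale); `wall = plaque` and a near-rigid outer wall are available, and the
  sensitivity grid sweeps $C_{10} \in \{0.01, 0.05, 0.2\}$ MPa.
* **Depth convention.** The evaluation point "0.8 mm from the lumen" is
  measured in the deformed configuration by default (results are reported
  post-revascularisation); the reference convention maps $R_i + 0.8$ mm
  forward through the kinematics and is also supported. At the default
  geometry the deformed-convention point sits at hoop stretch
  $\lambda_\theta \approx 1.553$.
* **Outer radius.** The printed wall thickness (0.48 mm) and the printed
  diameters (implying 0.46 mm) disagree by 0.02 mm; the default uses half
  the SFA diameter, with `useWallThickness = TRUE` honouring the printed
  thickness.

## Failure assessment

Each group's ultimate mechanically induced failure point (mean stretch and
mean Cauchy stress, with SDs where reported) is compared against the maximum
principal stress at the evaluation depth. The comparison uses the mean as a
single failure line; exceedance is strict, so a state exactly at the mean is
not failed (a documented, arbitrary tie-break). The default mode compares
stresses; stretch-based and either-quantity modes are available. SDs are
carried on the criterion objects for probabilistic margins but take no part
in the headline comparison.

## Synthetic data generator

The generator exists so that every stage is testable without any deposited
data; its defaults are the study conditions, not tuning knobs.

* **Curves** are sampled from a group's published coefficients on
  $[1, \lambda_{\rm fail}]$ with $\lambda_{\rm fail}$ drawn from the group's
  ultimate-failure distribution (truncated above 1.05), 50 points per curve,
  and *multiplicative* Gaussian stress noise at 5% CV — multiplicative
  because experimental soft-tissue stress scatter grows with the stress
  level.
* **Spectra** are sums of Gaussian absorbance bands on the instrument's
  2 cm⁻¹ grid: a CH₂ doublet (2925 cm⁻¹, σ = 9; 2855 cm⁻¹, σ = 3), an ester
  band (1730 cm⁻¹, σ = 6) and a single broad phosphate band (1030 cm⁻¹,
  σ = 30 — the ν₃ phosphate mode dominates the 1180–900 cm⁻¹ window), with
  closed-form areas arranged to give the target Ca:Li exactly, plus a smooth
  baseline (linear trend and a very broad background bump) and additive
  noise at 0.001 absorbance units, a typical 16-scan ATR noise floor.
* **Cohorts** pair one curve and one spectrum per sample with ground-truth
  labels; class Ca:Li targets are drawn uniformly within each class interval
  at a 0.1 margin from the boundaries.

What the generator does *not* emulate: preconditioning and rate effects,
sample-to-sample coefficient variability (curves within a group share one
generating model), ATR penetration-depth effects, water-vapour and CO₂
artefact bands, and correlated (non-white) spectral noise. Passing recovery
tests therefore demonstrate the correctness of the algorithms under the
assumed statistical structure, not robustness to every artefact of real
instruments and tissue.

## Problem sizes

Default sizes, chosen to keep every analysis at desk scale: inflation grid
4000 nodes (convergence verified by grid doubling against the closed form),
finite-difference cross-check 500 nodes, stability scans $10^4$ points,
noisy-recovery experiments 100 seeded replicates per group, FTIR accuracy
experiments 200 seeded spectra, cohort size 20 (7/6/7 across the three
femoral classes).

## Known limitations

* The concentric, residual-stress-free, cap-free two-layer ring is a
  deliberate idealisation for comparing material models; it is not a
  patient-specific stress predictor. (Femoral plaques are typically heavily
  fibrocalcific without a classical fibrous cap, which motivates the
  cap-free layout.)
* Stresses in the first ~0.1 mm above the lumen are dominated by the
  prescribed-displacement boundary condition and the extreme extrapolation
  of the strain energy functions; the 0.8 mm evaluation depth deliberately
  avoids this layer, and numbers quoted nearer the lumen should not be
  interpreted quantitatively.
* The headline fold change depends on the three undetermined conventions
  above; under the documented defaults it is computed by
  `scripts/acceptance.R`, and its order of magnitude (two orders above
  unity) is stable across the whole sensitivity grid, which is the robust
  scientific conclusion.
* $C_{10}$ of stiff, short-range material groups is structurally
  non-identifiable from noisy curves (see the fitting caveat).
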