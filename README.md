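# plaqueMech

Hyperelastic material models and revascularisation stress analysis for
atherosclerotic plaque tissue.

## The problem

Mechanical characterisations of *femoral* atherosclerotic plaque are rare,
so finite-element studies of femoral angioplasty and stenting commonly
substitute material data measured on *aortic* plaque. The two tissues differ
sharply — femoral plaques are heavily calcified, fibrotic and soft in the
large-strain regime, while aortic fibrous-cap samples stiffen like healthy
intima. plaqueMech is for vascular biomechanics researchers who want to
quantify what that substitution does to simulation results: it builds Yeoh
material models from planar-shear stress–stretch data, grades plaques by
FTIR calcification content, simulates the revascularisation of an idealised
concentric femoral stenosis with any of the material models, and compares
the resulting plaque stresses against each group's ultimate failure point.

## The model in brief

Plaque and wall are isotropic, incompressible, hyperelastic, with the
third-order reduced-polynomial (Yeoh) strain energy function

    Psi(I1) = C10 (I1 - 3) + C20 (I1 - 3)^2 + C30 (I1 - 3)^3

In planar shear (principal stretches (λ, 1, 1/λ), I1 = λ² + 1 + λ⁻²) the
loading-direction Cauchy stress is σ = 2(λ² − λ⁻²) ∂Ψ/∂I1; coefficients are
recovered by stability-constrained bounded least squares. FTIR spectra are
reduced to the calcification-to-lipid peak-area ratio
Ca:Li = A(1180–900 cm⁻¹) / [A(2972–2845 cm⁻¹) + A(~1730 cm⁻¹)], which
grades plaques as lightly (1 < Ca:Li < 1.5), moderately (1.5 ≤ Ca:Li < 2)
or heavily (2 ≤ Ca:Li < 3) calcified. The revascularisation of a concentric
two-layer ring (plaque + wall) is solved exactly in its 1D axisymmetric
plane-strain reduction: incompressible kinematics r = √(R² + ri² − Ri²) and
radial equilibrium dσrr/dr = (σθθ − σrr)/r integrated from the traction-free
outer surface. See the methods vignette
(`vignettes/plaque-material-models.Rmd`) for assumptions, defaults and
numerical choices.

## Worked example

```r
library(plaqueMech)

geom <- defaultGeometry()          # 6.87 / 5.95 mm vessel, 90% -> 10% stenosis
mats <- plaqueMaterials()          # six published Yeoh coefficient sets

cmp <- compareMaterials(geom, mats[c("heavily", "calcified_aortic")])
cmp$stresses
#>           material sigma_max_principal_MPa
#> 1          heavily               0.1036954
#> 2 calcified_aortic              35.5235236
cmp$ratios["calcified_aortic", "heavily"]
#> [1] 342.5758
```

Revascularising the same 90% femoral stenosis predicts ~0.10 MPa of maximum
principal stress 0.8 mm into the plaque when the plaque carries the
vessel-appropriate heavily calcified femoral model, but ~35.5 MPa — a
~343-fold increase — when the commonly borrowed calcified aortic model is
used instead. Checked against each group's ultimate failure stress:

```r
stresses <- vapply(mats, function(m)
  stressAtDepth(solveRevascularisation(geom, m), 0.8), numeric(1))
failureReport(stresses)$summary
#>    origin n_failed n_total
#> 1  aortic        3       3
#> 2 femoral        0       3
```

Every aortic-based simulation predicts tissue failure at that point; no
femoral-based simulation does. The full pipeline — material table, six
stress profiles, fold changes, failure report, sensitivity appendix and run
manifest — is one call: `runStudy(list(out_dir = "study-out"))`.

Fitting and classification work the same way from your own data:

```r
crv <- StressStretchCurve(lam, stress, group = "heavily")  # or readSpectrum()
fitYeoh(crv)
#> FitResult
#> YeohModel 'heavily'
#>   C10 = 0.0462 MPa, C20 = -0.0147 MPa, C30 = 0.00495 MPa
#>   R^2 = 1, stable = TRUE, residual norm = 5.979e-17 MPa

sp <- generateFtirSpectrum(2.3, seed = 11)   # synthetic ATR-FTIR spectrum
classifyCaLi(caLiRatio(sp))
#> [1] "heavily"
```

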