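# shared fixtures: printed materials, ultimate stretches, noiseless curves

fixMaterials <- plaqueMaterials()
fixCriteria <- failureCriteria()

fixUltimate <- vapply(fixCriteria, function(cr) cr@stretchMean, numeric(1))

# noiseless planar-shear curve sampled directly from a model
makeCurve <- function(model, lamMax, n = 50, group = "unknown",
                      sampleId = "fixture") {
  lam <- seq(1, lamMax, length.out = n)
  StressStretchCurve(lam, cauchyStressPlanarShear(lam, model),
                     sampleId = sampleId, group = group)
}
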