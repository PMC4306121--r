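## Central S4 containers. All validity checks mirror the physical constraints
## of the quantities they hold; units are MPa / mm / cm^-1 throughout.

#' Known plaque group labels
#'
#' Three femoral calcification grades (from FTIR classification), three aortic
#' histology-based groups, and `"unknown"`.
#'
#' @return Character vector of admissible group labels.
#' @export
plaqueGroups <- function() {
  c("lightly", "moderately", "heavily",
    "calcified_aortic", "cellular_aortic", "hypocellular_aortic",
    "unknown")
}

# ---------------------------------------------------------------- YeohModel

#' Yeoh hyperelastic material model
#'
#' Third-order reduced-polynomial strain energy function
#' \eqn{\Psi(I_1) = \sum_{i=1}^{3} C_{i0} (I_1 - 3)^i} with stress-like
#' coefficients in MPa. `c10` must be positive (initial shear stiffness);
#' negative `c20` is admissible and occurs in the femoral plaque groups.
#'
#' @slot c10,c20,c30 Material coefficients (MPa).
#' @slot label Free-text material name.
#' @export
setClass("YeohModel",
  representation(c10 = "numeric", c20 = "numeric", c30 = "numeric",
                 label = "character"),
  prototype(label = ""))

setValidity("YeohModel", function(object) {
  msg <- character()
  for (s in c("c10", "c20", "c30")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v))
      msg <- c(msg, sprintf("'%s' must be a single finite number", s))
  }
  if (length(object@c10) == 1L && is.finite(object@c10) && object@c10 <= 0)
    msg <- c(msg, "'c10' must be > 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn YeohModel Constructor.
#' @param c10,c20,c30 Coefficients (MPa).
#' @param label Material name.
#' @export
YeohModel <- function(c10, c20 = 0, c30 = 0, label = "") {
  new("YeohModel", c10 = as.numeric(c10), c20 = as.numeric(c20),
      c30 = as.numeric(c30), label = as.character(label))
}

#' Extract Yeoh coefficients as a named numeric vector
#'
#' @param model A [YeohModel-class] object.
#' @return Named numeric `c(c10 = , c20 = , c30 = )` in MPa.
#' @export
yeohCoefficients <- function(model) {
  stopifnot(is(model, "YeohModel"))
  c(c10 = model@c10, c20 = model@c20, c30 = model@c30)
}

setMethod("show", "YeohModel", function(object) {
  cat(sprintf("YeohModel%s\n",
              if (nzchar(object@label)) paste0(" '", object@label, "'") else ""))
  cat(sprintf("  C10 = %.4g MPa, C20 = %.4g MPa, C30 = %.4g MPa\n",
              object@c10, object@c20, object@c30))
})

# ------------------------------------------------------- StressStretchCurve

#' Planar-shear stress-stretch curve
#'
#' One sample's (experimental or synthetic) planar-shear response: ordered
#' stretch ratios starting at 1 with matching Cauchy stresses (MPa). The
#' reference state must carry zero stress.
#'
#' @slot stretch Strictly increasing stretch ratios, first value 1 (tol 1e-6).
#' @slot stress Cauchy stresses (MPa); at stretch 1 zero within 1e-3 MPa.
#' @slot sampleId Free-text identifier.
#' @slot group One of [plaqueGroups()].
#' @export
setClass("StressStretchCurve",
  representation(stretch = "numeric", stress = "numeric",
                 sampleId = "character", group = "character"),
  prototype(sampleId = "", group = "unknown"))

setValidity("StressStretchCurve", function(object) {
  msg <- character()
  n <- length(object@stretch)
  if (n != length(object@stress))
    msg <- c(msg, "'stretch' and 'stress' must have equal length")
  if (n < 3L) msg <- c(msg, "need at least 3 points")
  if (n >= 2L && any(diff(object@stretch) <= 0))
    msg <- c(msg, "'stretch' must be strictly increasing")
  if (n >= 1L && abs(object@stretch[1L] - 1) > 1e-6)
    msg <- c(msg, "first stretch must equal 1 (tolerance 1e-6)")
  if (n >= 1L && is.finite(object@stress[1L]) && abs(object@stress[1L]) > 1e-3)
    msg <- c(msg, "stress at stretch 1 must be 0 within 1e-3 MPa")
  if (!object@group %in% plaqueGroups())
    msg <- c(msg, sprintf("unknown group '%s'", object@group))
  if (length(msg)) msg else TRUE
})

#' @describeIn StressStretchCurve Constructor.
#' @param stretch,stress Numeric vectors (see slots).
#' @param sampleId,group See slots.
#' @export
StressStretchCurve <- function(stretch, stress, sampleId = "",
                               group = "unknown") {
  new("StressStretchCurve", stretch = as.numeric(stretch),
      stress = as.numeric(stress), sampleId = as.character(sampleId),
      group = as.character(group))
}

setMethod("show", "StressStretchCurve", function(object) {
  cat(sprintf("StressStretchCurve '%s' (group: %s)\n", object@sampleId,
              object@group))
  cat(sprintf("  %d points, stretch 1..%.4g, peak stress %.4g MPa\n",
              length(object@stretch), max(object@stretch),
              max(abs(object@stress))))
})

#' @export
#' @method as.data.frame StressStretchCurve
as.data.frame.StressStretchCurve <- function(x, ...) {
  data.frame(stretch = x@stretch, stress_MPa = x@stress,
             sample_id = x@sampleId, group = x@group)
}

# ------------------------------------------------------------------ FitResult

#' Result of a Yeoh coefficient fit
#'
#' @slot model Fitted [YeohModel-class].
#' @slot rSquared Coefficient of determination in stress space (NA when the
#'   input stresses are constant and R-squared is undefined).
#' @slot stable Outcome of [checkStability()] over the fitted stretch range.
#' @slot residualNorm Root of the residual sum of squares (MPa).
#' @export
setClass("FitResult",
  representation(model = "YeohModel", rSquared = "numeric",
                 stable = "logical", residualNorm = "numeric"))

setValidity("FitResult", function(object) {
  if (length(object@rSquared) == 1L && is.finite(object@rSquared) &&
      object@rSquared > 1 + 1e-12)
    return("rSquared must be <= 1")
  TRUE
})

setMethod("show", "FitResult", function(object) {
  cat("FitResult\n")
  show(object@model)
  cat(sprintf("  R^2 = %s, stable = %s, residual norm = %.4g MPa\n",
              format(object@rSquared, digits = 6), object@stable,
              object@residualNorm))
})

# --------------------------------------------------------------- FTIRSpectrum

#' ATR-FTIR absorbance spectrum
#'
#' @slot wavenumber Strictly monotone wavenumbers (cm^-1) within 700-4000.
#' @slot absorbance Matching absorbance values (absorbance units).
#' @slot sampleId Free-text identifier.
#' @slot meta List of generator metadata (ground-truth band areas and target
#'   Ca:Li for synthetic spectra); empty for measured data.
#' @export
setClass("FTIRSpectrum",
  representation(wavenumber = "numeric", absorbance = "numeric",
                 sampleId = "character", meta = "list"),
  prototype(sampleId = "", meta = list()))

setValidity("FTIRSpectrum", function(object) {
  msg <- character()
  if (length(object@wavenumber) != length(object@absorbance))
    msg <- c(msg, "'wavenumber' and 'absorbance' must have equal length")
  if (length(object@wavenumber) >= 2L) {
    d <- diff(object@wavenumber)
    if (!(all(d > 0) || all(d < 0)))
      msg <- c(msg, "'wavenumber' must be strictly monotone")
  }
  rng <- range(object@wavenumber)
  if (rng[1] < 700 - 1e-9 || rng[2] > 4000 + 1e-9)
    msg <- c(msg, "wavenumber range must lie within 700-4000 cm^-1")
  if (length(msg)) msg else TRUE
})

#' @describeIn FTIRSpectrum Constructor. Descending acquisition order is
#'   accepted and stored ascending.
#' @param wavenumber,absorbance,sampleId,meta See slots.
#' @export
FTIRSpectrum <- function(wavenumber, absorbance, sampleId = "", meta = list()) {
  wavenumber <- as.numeric(wavenumber)
  absorbance <- as.numeric(absorbance)
  if (length(wavenumber) >= 2L && wavenumber[1L] > wavenumber[length(wavenumber)]) {
    wavenumber <- rev(wavenumber)
    absorbance <- rev(absorbance)
  }
  new("FTIRSpectrum", wavenumber = wavenumber, absorbance = absorbance,
      sampleId = as.character(sampleId), meta = meta)
}

setMethod("show", "FTIRSpectrum", function(object) {
  cat(sprintf("FTIRSpectrum '%s': %d points, %.0f-%.0f cm^-1\n",
              object@sampleId, length(object@wavenumber),
              min(object@wavenumber), max(object@wavenumber)))
})

# ------------------------------------------------------------- VesselGeometry

#' Idealised concentric stenosis geometry
#'
#' Reference-configuration dimensions of a concentric two-layer (plaque +
#' media/adventitia wall) femoral artery segment. Stenosis percentages are
#' diameter obstructions relative to either the healthy lumen diameter
#' (`stenosisReference = "healthy_lumen"`, the default) or the outer SFA
#' diameter (`"sfa"`). By default the outer wall radius is taken as half the
#' SFA diameter; set `useWallThickness = TRUE` to honour the printed wall
#' thickness instead (the two differ by 0.02 mm for the default dimensions).
#'
#' @slot sfaDiameter Superficial femoral artery outer diameter (mm).
#' @slot lumenDiameter Healthy lumen diameter (mm).
#' @slot wallThickness Media/adventitia wall thickness (mm).
#' @slot initialStenosisPct,finalStenosisPct Diameter stenosis (%).
#' @slot stenosisReference `"healthy_lumen"` or `"sfa"`.
#' @slot useWallThickness Logical; see above.
#' @export
setClass("VesselGeometry",
  representation(sfaDiameter = "numeric", lumenDiameter = "numeric",
                 wallThickness = "numeric", initialStenosisPct = "numeric",
                 finalStenosisPct = "numeric", stenosisReference = "character",
                 useWallThickness = "logical"),
  prototype(stenosisReference = "healthy_lumen", useWallThickness = FALSE))

setValidity("VesselGeometry", function(object) {
  msg <- character()
  if (!(object@lumenDiameter > 0 && object@lumenDiameter < object@sfaDiameter))
    msg <- c(msg, "need 0 < lumenDiameter < sfaDiameter")
  if (object@wallThickness <= 0) msg <- c(msg, "wallThickness must be > 0")
  if (!(object@finalStenosisPct >= 0 &&
        object@finalStenosisPct <= object@initialStenosisPct &&
        object@initialStenosisPct < 100))
    msg <- c(msg, "need 0 <= finalStenosisPct <= initialStenosisPct < 100")
  if (!object@stenosisReference %in% c("healthy_lumen", "sfa"))
    msg <- c(msg, "stenosisReference must be 'healthy_lumen' or 'sfa'")
  if (length(msg)) return(msg)
  rr <- tryCatch(referenceConfiguration(object), error = function(e) NULL)
  if (is.null(rr) || !(rr["Ri"] < rr["Rp"] && rr["Rp"] < rr["Ro"]))
    msg <- c(msg, "reference radii must satisfy Ri < Rp < Ro")
  if (length(msg)) msg else TRUE
})

#' @describeIn VesselGeometry Constructor.
#' @param sfaDiameter,lumenDiameter,wallThickness,initialStenosisPct,finalStenosisPct,stenosisReference,useWallThickness
#'   See slots.
#' @export
VesselGeometry <- function(sfaDiameter, lumenDiameter, wallThickness,
                           initialStenosisPct, finalStenosisPct,
                           stenosisReference = "healthy_lumen",
                           useWallThickness = FALSE) {
  new("VesselGeometry", sfaDiameter = as.numeric(sfaDiameter),
      lumenDiameter = as.numeric(lumenDiameter),
      wallThickness = as.numeric(wallThickness),
      initialStenosisPct = as.numeric(initialStenosisPct),
      finalStenosisPct = as.numeric(finalStenosisPct),
      stenosisReference = stenosisReference,
      useWallThickness = isTRUE(useWallThickness))
}

setMethod("show", "VesselGeometry", function(object) {
  rr <- referenceConfiguration(object)
  cat(sprintf("VesselGeometry: SFA %.2f mm, lumen %.2f mm, wall %.2f mm\n",
              object@sfaDiameter, object@lumenDiameter, object@wallThickness))
  cat(sprintf("  stenosis %g%% -> %g%% of %s diameter\n",
              object@initialStenosisPct, object@finalStenosisPct,
              sub("_", " ", object@stenosisReference)))
  cat(sprintf("  reference radii: Ri = %.4f, Rp = %.4f, Ro = %.4f mm\n",
              rr["Ri"], rr["Rp"], rr["Ro"]))
})

# --------------------------------------------------------- RadialStressProfile

#' Radial stress profile after revascularisation
#'
#' Stress components along the radial line of interest (lumen to outer wall)
#' in the deformed configuration. `sigmaMaxPrincipal` is the pointwise maximum
#' of the radial, hoop and axial components.
#'
#' @slot radius Deformed radial positions (mm), lumen outward.
#' @slot referenceRadius Matching reference radial positions (mm).
#' @slot sigmaRR,sigmaTT,sigmaZZ,sigmaMaxPrincipal Stress components (MPa).
#' @slot depthFromLumen `radius - lumenRadius` (mm).
#' @slot lumenRadius,interfaceRadius,outerRadius Deformed landmark radii (mm).
#' @slot refLumenRadius Reference (pre-revascularisation) lumen radius (mm).
#' @slot plaqueLabel,wallLabel Material labels.
#' @export
setClass("RadialStressProfile",
  representation(radius = "numeric", referenceRadius = "numeric",
                 sigmaRR = "numeric", sigmaTT = "numeric", sigmaZZ = "numeric",
                 sigmaMaxPrincipal = "numeric", depthFromLumen = "numeric",
                 lumenRadius = "numeric", interfaceRadius = "numeric",
                 outerRadius = "numeric", refLumenRadius = "numeric",
                 plaqueLabel = "character", wallLabel = "character"))

setValidity("RadialStressProfile", function(object) {
  msg <- character()
  n <- length(object@radius)
  for (s in c("referenceRadius", "sigmaRR", "sigmaTT", "sigmaZZ",
              "sigmaMaxPrincipal", "depthFromLumen"))
    if (length(slot(object, s)) != n)
      msg <- c(msg, sprintf("'%s' must match 'radius' in length", s))
  if (n && abs(object@sigmaRR[n]) > 1e-8)
    msg <- c(msg, "radial stress at the outer surface must vanish (tol 1e-8 MPa)")
  if (n && max(abs(object@sigmaMaxPrincipal -
                   pmax(object@sigmaRR, object@sigmaTT, object@sigmaZZ))) > 1e-12)
    msg <- c(msg, "sigmaMaxPrincipal must be the pointwise max of the components")
  if (length(msg)) msg else TRUE
})

setMethod("show", "RadialStressProfile", function(object) {
  cat(sprintf("RadialStressProfile (plaque: %s | wall: %s)\n",
              object@plaqueLabel, object@wallLabel))
  cat(sprintf("  %d nodes, r = %.4f..%.4f mm (interface %.4f mm)\n",
              length(object@radius), object@lumenRadius, object@outerRadius,
              object@interfaceRadius))
  cat(sprintf("  max principal stress: %.4g MPa at the lumen\n",
              max(object@sigmaMaxPrincipal)))
})

#' @export
#' @method as.data.frame RadialStressProfile
as.data.frame.RadialStressProfile <- function(x, ...) {
  data.frame(radius_mm = x@radius, depth_mm = x@depthFromLumen,
             reference_radius_mm = x@referenceRadius,
             sigma_rr_MPa = x@sigmaRR, sigma_tt_MPa = x@sigmaTT,
             sigma_zz_MPa = x@sigmaZZ,
             sigma_max_principal_MPa = x@sigmaMaxPrincipal)
}

# ------------------------------------------------------------ FailureCriterion

#' Ultimate mechanically induced failure criterion
#'
#' Group-mean ultimate stretch and Cauchy stress at rupture, with standard
#' deviations where reported (NA otherwise).
#'
#' @slot group Material group label.
#' @slot stretchMean,stretchSD Ultimate stretch ratio (dimensionless).
#' @slot stressMean,stressSD Ultimate Cauchy stress (MPa).
#' @export
setClass("FailureCriterion",
  representation(group = "character", stretchMean = "numeric",
                 stretchSD = "numeric", stressMean = "numeric",
                 stressSD = "numeric"))

setValidity("FailureCriterion", function(object) {
  msg <- character()
  if (!is.finite(object@stretchMean) || object@stretchMean <= 1)
    msg <- c(msg, "ultimate stretch mean must be > 1")
  if (!is.finite(object@stressMean) || object@stressMean <= 0)
    msg <- c(msg, "ultimate stress mean must be > 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn FailureCriterion Constructor.
#' @param group,stretchMean,stretchSD,stressMean,stressSD See slots.
#' @export
FailureCriterion <- function(group, stretchMean, stressMean,
                             stretchSD = NA_real_, stressSD = NA_real_) {
  new("FailureCriterion", group = as.character(group),
      stretchMean = as.numeric(stretchMean), stretchSD = as.numeric(stretchSD),
      stressMean = as.numeric(stressMean), stressSD = as.numeric(stressSD))
}

setMethod("show", "FailureCriterion", function(object) {
  fmt <- function(m, s) if (is.na(s)) sprintf("%.3g", m) else
    sprintf("%.3g ± %.3g", m, s)
  cat(sprintf("FailureCriterion '%s': ultimate stretch %s, stress %s MPa\n",
              object@group, fmt(object@stretchMean, object@stretchSD),
              fmt(object@stressMean, object@stressSD)))
})
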