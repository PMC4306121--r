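## Published study inputs: the six Yeoh coefficient sets, the ultimate
## failure statistics of each group, and the idealised vessel dimensions.
## These tables are the study's inputs; fitting can regenerate the
## coefficients from (synthetic or measured) curves via buildMaterialTable().

#' Femoral plaque material models
#'
#' Yeoh coefficient sets for the three FTIR-graded femoral plaque groups
#' (fitted to planar-shear group-average curves).
#'
#' @return Named list of [YeohModel-class]: `lightly`, `moderately`,
#'   `heavily`.
#' @export
femoralMaterials <- function() {
  list(
    lightly = YeohModel(4.98e-2, -6.19e-3, 8.98e-4, "lightly calcified femoral"),
    moderately = YeohModel(1.35e-1, -2.84e-2, 4.90e-3, "moderately calcified femoral"),
    heavily = YeohModel(4.62e-2, -1.47e-2, 4.95e-3, "heavily calcified femoral"))
}

#' Aortic plaque material models
#'
#' Yeoh coefficient sets for the three histology-graded aortic plaque groups
#' (fitted to literature average curves), widely used as stand-ins for
#' femoral plaque in the modelling literature.
#'
#' @return Named list of [YeohModel-class]: `calcified_aortic`,
#'   `cellular_aortic`, `hypocellular_aortic`.
#' @export
aorticMaterials <- function() {
  list(
    calcified_aortic = YeohModel(1.41e-3, 4.73, 8.51e-1, "calcified aortic"),
    cellular_aortic = YeohModel(4.84e-3, 3.59e-1, 6.08e-1, "cellular aortic"),
    hypocellular_aortic = YeohModel(2.20e-1, 5.09e-1, 6.19e-1, "hypocellular aortic"))
}

#' All six plaque material models
#'
#' @return Named list combining [femoralMaterials()] and [aorticMaterials()].
#' @export
plaqueMaterials <- function() c(femoralMaterials(), aorticMaterials())

#' Ultimate failure criteria per plaque group
#'
#' Group-mean (± SD where reported) stretch ratio and Cauchy stress at
#' ultimate mechanically induced failure. The hypocellular aortic group has
#' no reported SDs.
#'
#' @return Named list of [FailureCriterion-class], one per group, in the same
#'   order as [plaqueMaterials()].
#' @export
failureCriteria <- function() {
  list(
    lightly = FailureCriterion("lightly", 2.16, 0.3, 0.09, 0.01),
    moderately = FailureCriterion("moderately", 1.75, 0.43, 0.19, 0.11),
    heavily = FailureCriterion("heavily", 1.55, 0.16, 0.21, 0.04),
    calcified_aortic = FailureCriterion("calcified_aortic", 1.19, 0.52, 0.04, 0.34),
    cellular_aortic = FailureCriterion("cellular_aortic", 1.42, 0.74, 0.14, 0.27),
    hypocellular_aortic = FailureCriterion("hypocellular_aortic", 1.23, 0.67))
}

#' Default idealised femoral stenosis geometry
#'
#' SFA diameter 6.87 mm, healthy lumen 5.95 mm, wall thickness 0.48 mm,
#' revascularised from a 90% to a 10% diameter stenosis. Stenosis
#' percentages are referenced to the healthy lumen diameter by default
#' (referencing them to the SFA diameter would make the final lumen exceed
#' the healthy lumen, which is inconsistent for a concentric plaque; the
#' `"sfa"` convention remains available). The outer radius defaults to half
#' the SFA diameter (implying a 0.46 mm wall); `useWallThickness = TRUE` on
#' [VesselGeometry()] honours the printed 0.48 mm instead.
#'
#' @param stenosisReference `"healthy_lumen"` (default) or `"sfa"`.
#' @param useWallThickness See [VesselGeometry-class].
#' @return A [VesselGeometry-class].
#' @export
defaultGeometry <- function(stenosisReference = "healthy_lumen",
                            useWallThickness = FALSE) {
  VesselGeometry(sfaDiameter = 6.87, lumenDiameter = 5.95,
                 wallThickness = 0.48, initialStenosisPct = 90,
                 finalStenosisPct = 10,
                 stenosisReference = stenosisReference,
                 useWallThickness = useWallThickness)
}

#' Default healthy wall material
#'
#' The media/adventitia wall material is not part of the plaque data set; a
#' neo-Hookean model with C10 = 0.05 MPa (soft-tissue shear-stiffness scale)
#' is used by default. Pass a different `c10`, or use the plaque model itself
#' or a near-rigid wall, to probe sensitivity (see [runStudy()]).
#'
#' @param c10 Neo-Hookean coefficient (MPa), default 0.05.
#' @return A [YeohModel-class].
#' @export
defaultWall <- function(c10 = 0.05) {
  YeohModel(c10, 0, 0, sprintf("healthy wall (neo-Hookean, C10 = %g MPa)", c10))
}
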