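## Displacement-driven revascularisation of a concentric two-layer vessel.
## The quarter-symmetric plane-strain problem is axisymmetric, so the exact
## incompressible 1D radial reduction is solved instead of a 2D mesh:
## kinematics r = sqrt(R^2 + ri^2 - Ri^2) (annular area conservation with
## lambda_z = 1), radial equilibrium d(sigma_rr)/dr = (sigma_tt - sigma_rr)/r
## integrated inward from the traction-free outer surface.

#' Reference radii of the stenosed vessel
#'
#' Derives the reference (pre-revascularisation) radii from the geometry:
#' `Ri` the initial open lumen radius, `Rp` the plaque/wall interface (half
#' the healthy lumen diameter), `Ro` the outer wall radius. A stenosis of
#' p % of a reference diameter leaves an open lumen of (100 - p) % of it.
#'
#' @param geometry A [VesselGeometry-class].
#' @return Named numeric `c(Ri = , Rp = , Ro = )` in mm.
#' @export
referenceConfiguration <- function(geometry) {
  stopifnot(is(geometry, "VesselGeometry"))
  refR <- switch(geometry@stenosisReference,
                 healthy_lumen = geometry@lumenDiameter / 2,
                 sfa = geometry@sfaDiameter / 2,
                 stop("unknown stenosisReference"))
  Ri <- (1 - geometry@initialStenosisPct / 100) * refR
  Rp <- geometry@lumenDiameter / 2
  Ro <- if (geometry@useWallThickness) Rp + geometry@wallThickness
        else geometry@sfaDiameter / 2
  if (!(Ri > 0 && Ri < Rp && Rp < Ro))
    stop(sprintf("invalid radii ordering: Ri = %.4f, Rp = %.4f, Ro = %.4f",
                 Ri, Rp, Ro))
  c(Ri = Ri, Rp = Rp, Ro = Ro)
}

#' Final (post-revascularisation) lumen radius
#'
#' @inheritParams referenceConfiguration
#' @return Lumen radius (mm) at the final stenosis level.
#' @export
finalLumenRadius <- function(geometry) {
  stopifnot(is(geometry, "VesselGeometry"))
  refR <- switch(geometry@stenosisReference,
                 healthy_lumen = geometry@lumenDiameter / 2,
                 sfa = geometry@sfaDiameter / 2)
  (1 - geometry@finalStenosisPct / 100) * refR
}

#' Incompressible plane-strain radius map
#'
#' Deformed radius of the material circle at reference radius `R` when the
#' lumen moves from `Ri` to `ri`: \eqn{r = \sqrt{R^2 + r_i^2 - R_i^2}}. This
#' conserves every annular area (plane strain, \eqn{\lambda_z = 1},
#' incompressible), and reduces to the identity when `ri = Ri`.
#'
#' @param R Reference radius (mm), `>= Ri`; vectorised.
#' @param Ri Reference lumen radius (mm).
#' @param ri Deformed lumen radius (mm), > 0.
#' @return Deformed radius (mm).
#' @export
deformedRadiusMap <- function(R, Ri, ri) {
  if (any(!is.finite(R)) || any(R < Ri - 1e-12))
    stop("'R' must be >= Ri (material points inside the lumen do not exist)")
  if (!is.finite(ri) || ri <= 0) stop("'ri' must be positive")
  sqrt(pmax(R^2 + ri^2 - Ri^2, 0))
}

# inverse map: reference radius of the deformed position r
.referenceRadiusMap <- function(r, Ri, ri) sqrt(pmax(r^2 - ri^2 + Ri^2, 0))

#' Hoop-radial stress difference at a hoop stretch
#'
#' Standard incompressible plane-strain relation
#' \eqn{\sigma_{\theta\theta} - \sigma_{rr} =
#' 2(\lambda_\theta^2 - \lambda_\theta^{-2})\,\partial\Psi/\partial I_1} with
#' \eqn{I_1 = \lambda_\theta^2 + \lambda_\theta^{-2} + 1}; the pressure-like
#' part of the stress cancels in the difference. Zero at
#' \eqn{\lambda_\theta = 1}.
#'
#' @param hoopStretch Positive hoop stretch(es) \eqn{\lambda_\theta}.
#' @param model A [YeohModel-class].
#' @return Stress difference (MPa).
#' @export
hoopStressDifference <- function(hoopStretch, model) {
  stopifnot(is(model, "YeohModel"))
  if (!length(hoopStretch) || any(!is.finite(hoopStretch)) ||
      any(hoopStretch <= 0))
    stop("'hoopStretch' must be positive and finite")
  i1 <- hoopStretch^2 + hoopStretch^-2 + 1
  2 * (hoopStretch^2 - hoopStretch^-2) * dPsidI1(i1, model)
}

#' Solve the revascularisation of the concentric stenosis
#'
#' Displaces the lumen surface from the initial-stenosis radius to the
#' final-stenosis radius under plane-strain incompressibility and integrates
#' the radial equilibrium equation
#' \eqn{d\sigma_{rr}/dr = (\sigma_{\theta\theta} - \sigma_{rr})/r} inward
#' from the traction-free outer surface on a grid geometrically refined
#' towards the lumen, where the hoop-stretch gradient is steepest. The axial
#' stress follows from plane strain:
#' \eqn{\sigma_{zz} = \sigma_{rr} +
#' 2\,\partial\Psi/\partial I_1\,(1 - \lambda_\theta^{-2})}.
#'
#' If a material is non-monotone over the induced stretch range the solve
#' proceeds with a warning: the strain energy function is then extrapolated
#' along its predicted path beyond the tested regime.
#'
#' @param geometry A [VesselGeometry-class].
#' @param plaque,wall [YeohModel-class] materials for the diseased layer
#'   (lumen to healthy-lumen interface) and the media/adventitia wall.
#' @param gridSize Number of radial nodes (default 4000, minimum 100).
#' @param clustering Geometric clustering strength towards the lumen
#'   (default 8; 0 gives a uniform grid).
#' @return A [RadialStressProfile-class].
#' @export
solveRevascularisation <- function(geometry, plaque, wall = defaultWall(),
                                   gridSize = 4000L, clustering = 8) {
  stopifnot(is(geometry, "VesselGeometry"), is(plaque, "YeohModel"),
            is(wall, "YeohModel"))
  if (gridSize < 100L) stop("'gridSize' must be at least 100")
  rr <- referenceConfiguration(geometry)
  Ri <- rr[["Ri"]]; Rp <- rr[["Rp"]]; Ro <- rr[["Ro"]]
  ri <- finalLumenRadius(geometry)
  ro <- deformedRadiusMap(Ro, Ri, ri)
  rp <- deformedRadiusMap(Rp, Ri, ri)
  # stability over the induced hoop-stretch range (largest at the lumen)
  ltMaxPlaque <- ri / Ri
  ltMaxWall <- max(rp / Rp, 1)
  for (chk in list(list(m = plaque, lt = ltMaxPlaque, what = "plaque"),
                   list(m = wall, lt = ltMaxWall, what = "wall"))) {
    if (chk$lt > 1 + 1e-12) {
      st <- checkStability(chk$m, c(1, chk$lt), nGrid = 2000L)
      if (!st$stable)
        warning(sprintf(
          "%s material '%s' non-monotone at stretch %.3f (induced range up to %.3f); extrapolating the SEF along its predicted path",
          chk$what, chk$m@label, st$firstViolation, chk$lt))
    }
  }
  # deformed-configuration grid, geometrically clustered at the lumen,
  # with the plaque/wall interface inserted exactly
  u <- seq(0, 1, length.out = gridSize)
  r <- if (clustering > 0)
    ri + (ro - ri) * (exp(clustering * u) - 1) / (exp(clustering) - 1)
  else ri + (ro - ri) * u
  r <- sort(unique(c(r, rp)))
  R <- .referenceRadiusMap(r, Ri, ri)
  R[length(R)] <- Ro; R[1] <- Ri  # guard rounding at the endpoints
  lt <- r / R
  inPlaque <- R <= Rp + 1e-12
  i1 <- lt^2 + lt^-2 + 1
  dpsi <- ifelse(inPlaque, dPsidI1(i1, plaque), dPsidI1(i1, wall))
  delta <- 2 * (lt^2 - lt^-2) * dpsi    # sigma_tt - sigma_rr
  f <- delta / r
  n <- length(r)
  seg <- 0.5 * (f[-1] + f[-n]) * diff(r)
  sigmaRR <- -rev(c(0, cumsum(rev(seg))))
  sigmaRR[n] <- 0
  sigmaTT <- sigmaRR + delta
  sigmaZZ <- sigmaRR + 2 * dpsi * (1 - lt^-2)
  new("RadialStressProfile",
      radius = r, referenceRadius = R, sigmaRR = sigmaRR, sigmaTT = sigmaTT,
      sigmaZZ = sigmaZZ,
      sigmaMaxPrincipal = pmax(sigmaRR, sigmaTT, sigmaZZ),
      depthFromLumen = r - ri, lumenRadius = ri, interfaceRadius = rp,
      outerRadius = ro, refLumenRadius = Ri,
      plaqueLabel = plaque@label, wallLabel = wall@label)
}

#' Equilibrium residual of a stress profile
#'
#' Central-difference check of
#' \eqn{d\sigma_{rr}/dr = (\sigma_{\theta\theta} - \sigma_{rr})/r} on the
#' profile's own grid, scaled by the profile's largest hoop-stress magnitude.
#'
#' @param profile A [RadialStressProfile-class].
#' @return Maximum scaled residual (dimensionless).
#' @export
equilibriumResidual <- function(profile) {
  stopifnot(is(profile, "RadialStressProfile"))
  r <- profile@radius
  n <- length(r)
  dd <- (profile@sigmaRR[3:n] - profile@sigmaRR[1:(n - 2)]) /
    (r[3:n] - r[1:(n - 2)])
  fmid <- (profile@sigmaTT[2:(n - 1)] - profile@sigmaRR[2:(n - 1)]) /
    r[2:(n - 1)]
  max(abs(dd - fmid)) / max(abs(profile@sigmaTT))
}

#' Maximum principal stress at a depth from the lumen
#'
#' Linear interpolation of the profile's maximum principal stress at a point
#' a given distance from the lumen surface. With `convention = "deformed"`
#' (default) the depth is measured in the deformed configuration
#' (`lumenRadius + depth`); with `"reference"` it is measured from the
#' pre-revascularisation lumen and mapped forward through the kinematics.
#'
#' @param profile A [RadialStressProfile-class].
#' @param depth Distance from the lumen (mm), within the vessel.
#' @param convention `"deformed"` or `"reference"`.
#' @return Maximum principal stress (MPa).
#' @export
stressAtDepth <- function(profile, depth,
                          convention = c("deformed", "reference")) {
  stopifnot(is(profile, "RadialStressProfile"))
  convention <- match.arg(convention)
  if (!is.finite(depth) || depth < 0) stop("'depth' must be >= 0")
  x <- switch(convention,
              deformed = profile@lumenRadius + depth,
              reference = deformedRadiusMap(profile@refLumenRadius + depth,
                                            profile@refLumenRadius,
                                            profile@lumenRadius))
  if (x > profile@outerRadius + 1e-9)
    stop(sprintf("depth %.3f mm lies outside the vessel (outer radius %.4f mm)",
                 depth, profile@outerRadius))
  approx(profile@radius, profile@sigmaMaxPrincipal, xout = x)$y
}

#' Compare plaque material models at a fixed depth
#'
#' Solves the revascularisation once per plaque material (sharing one wall
#' model), extracts the maximum principal stress at the stated depth, and
#' tabulates all pairwise fold changes (row material / column material).
#'
#' @param geometry A [VesselGeometry-class].
#' @param plaques Named list of [YeohModel-class] plaque materials (>= 2).
#' @param wall Shared wall [YeohModel-class].
#' @param depth Depth from the lumen (mm), default 0.8.
#' @param convention Depth convention, see [stressAtDepth()].
#' @param gridSize Radial nodes per solve.
#' @return List with `stresses` (data.frame of material and stress at depth),
#'   `ratios` (matrix of pairwise fold changes) and `profiles` (the solved
#'   [RadialStressProfile-class] objects).
#' @export
compareMaterials <- function(geometry, plaques, wall = defaultWall(),
                             depth = 0.8,
                             convention = c("deformed", "reference"),
                             gridSize = 4000L) {
  convention <- match.arg(convention)
  if (length(plaques) < 2L) stop("need at least 2 plaque materials")
  if (is.null(names(plaques)) || any(!nzchar(names(plaques))))
    names(plaques) <- vapply(plaques, slot, character(1), "label")
  profiles <- lapply(plaques, function(m)
    solveRevascularisation(geometry, m, wall, gridSize = gridSize))
  s <- vapply(profiles, stressAtDepth, numeric(1), depth = depth,
              convention = convention)
  ratios <- outer(s, s, `/`)
  dimnames(ratios) <- list(names(plaques), names(plaques))
  list(stresses = data.frame(material = names(plaques),
                             sigma_max_principal_MPa = unname(s),
                             row.names = NULL),
       ratios = ratios, profiles = profiles)
}
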