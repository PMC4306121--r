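## Yeoh constitutive relations for incompressible planar shear.
## Deformation: principal stretches (lambda, 1, 1/lambda), so
## I1 = lambda^2 + 1 + lambda^-2 and the loading-direction Cauchy stress is
## sigma = 2 (lambda^2 - lambda^-2) dPsi/dI1.

#' First strain invariant for planar shear
#'
#' For the planar-shear (pure shear) deformation with principal stretches
#' \eqn{(\lambda, 1, 1/\lambda)},
#' \eqn{I_1 = \lambda^2 + 1 + \lambda^{-2} \ge 3}, with equality only in the
#' identity configuration \eqn{\lambda = 1}. Symmetric under
#' \eqn{\lambda \leftrightarrow 1/\lambda}.
#'
#' @param stretch Positive principal stretch ratio(s).
#' @return First invariant \eqn{I_1} (dimensionless, >= 3).
#' @examples
#' firstInvariantPlanarShear(c(1, 2, 0.5))
#' @export
firstInvariantPlanarShear <- function(stretch) {
  if (!length(stretch) || any(!is.finite(stretch)) || any(stretch <= 0))
    stop("'stretch' must be positive and finite")
  stretch^2 + 1 + stretch^-2
}

.checkI1 <- function(i1) {
  if (!length(i1) || any(!is.finite(i1)) || any(i1 < 3 - 1e-12))
    stop("'i1' must be >= 3 (undeformed state has I1 = 3)")
  pmax(i1, 3)
}

#' Yeoh strain energy density
#'
#' \eqn{\Psi(I_1) = C_{10}(I_1-3) + C_{20}(I_1-3)^2 + C_{30}(I_1-3)^3}, zero
#' in the undeformed state.
#'
#' @param i1 First invariant(s), >= 3.
#' @param model A [YeohModel-class].
#' @return Energy density (MPa).
#' @export
strainEnergy <- function(i1, model) {
  stopifnot(is(model, "YeohModel"))
  x <- .checkI1(i1) - 3
  model@c10 * x + model@c20 * x^2 + model@c30 * x^3
}

#' Derivative of the Yeoh energy with respect to the first invariant
#'
#' \eqn{\partial\Psi/\partial I_1 = C_{10} + 2C_{20}(I_1-3) + 3C_{30}(I_1-3)^2}.
#'
#' @inheritParams strainEnergy
#' @return Derivative (MPa).
#' @export
dPsidI1 <- function(i1, model) {
  stopifnot(is(model, "YeohModel"))
  x <- .checkI1(i1) - 3
  model@c10 + 2 * model@c20 * x + 3 * model@c30 * x^2
}

# second derivative, used by the analytic stability tangent
.d2PsidI12 <- function(i1, model) {
  x <- .checkI1(i1) - 3
  2 * model@c20 + 6 * model@c30 * x
}

#' Cauchy stress in incompressible planar shear
#'
#' Loading-direction Cauchy stress
#' \eqn{\sigma = 2(\lambda^2 - \lambda^{-2})\,\partial\Psi/\partial I_1} for an
#' incompressible planar-shear deformation. Zero at \eqn{\lambda = 1}; its sign
#' follows \eqn{\mathrm{sign}(\lambda - 1)} for materials with positive
#' tangent stiffness.
#'
#' @param stretch Positive stretch ratio(s).
#' @param model A [YeohModel-class].
#' @return Cauchy stress (MPa).
#' @examples
#' cauchyStressPlanarShear(1.5, YeohModel(1))  # 2*(2.25 - 4/9) = 3.6111 MPa
#' @export
cauchyStressPlanarShear <- function(stretch, model) {
  stopifnot(is(model, "YeohModel"))
  if (!length(stretch) || any(!is.finite(stretch)) || any(stretch <= 0))
    stop("'stretch' must be positive and finite")
  i1 <- stretch^2 + 1 + stretch^-2
  2 * (stretch^2 - stretch^-2) * dPsidI1(i1, model)
}

# analytic tangent d(sigma)/d(lambda) of the planar-shear stress
.planarShearTangent <- function(stretch, model) {
  i1 <- stretch^2 + 1 + stretch^-2
  di1 <- 2 * stretch - 2 * stretch^-3
  2 * (2 * stretch + 2 * stretch^-3) * dPsidI1(i1, model) +
    2 * (stretch^2 - stretch^-2) * .d2PsidI12(i1, model) * di1
}

#' Material stability check (monotone planar-shear response)
#'
#' A coefficient set is accepted as stable over a stretch interval when the
#' planar-shear Cauchy stress is strictly increasing in stretch there, i.e.
#' the analytic tangent stiffness is positive on a dense grid. This is the
#' Drucker-type criterion used to constrain fits: a softening (non-monotone)
#' fitted response would do non-positive incremental work.
#'
#' @param model A [YeohModel-class].
#' @param stretchRange Closed interval `c(lo, hi)` with `0 < lo <= 1 <= hi`.
#' @param nGrid Number of grid points (default 1e4).
#' @return List with `stable` (logical) and `firstViolation` (smallest grid
#'   stretch with non-positive tangent, or `NA` when stable).
#' @examples
#' checkStability(YeohModel(1), c(0.7, 2.5))$stable          # neo-Hookean
#' checkStability(YeohModel(0.01, -10), c(1, 2))$stable      # softening
#' @export
checkStability <- function(model, stretchRange, nGrid = 1e4) {
  stopifnot(is(model, "YeohModel"))
  if (length(stretchRange) != 2L || any(!is.finite(stretchRange)) ||
      stretchRange[1] <= 0 || stretchRange[1] > stretchRange[2])
    stop("'stretchRange' must be a valid positive interval c(lo, hi)")
  if (!(stretchRange[1] <= 1 && 1 <= stretchRange[2]))
    stop("'stretchRange' must contain the identity stretch 1")
  grid <- seq(stretchRange[1], stretchRange[2], length.out = max(2L, nGrid))
  tang <- .planarShearTangent(grid, model)
  bad <- which(tang <= 0)
  if (length(bad)) list(stable = FALSE, firstViolation = grid[bad[1L]])
  else list(stable = TRUE, firstViolation = NA_real_)
}
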