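## Coefficient recovery from planar-shear data. The Yeoh planar-shear stress
## is linear in (C10, C20, C30); the fit is nonetheless run through a bounded
## Levenberg-Marquardt optimiser (minpack.lm) with seeded multi-start so the
## stability constraint can be enforced by rejection-and-restart without
## changing the least-squares objective.

# evaluate an expression with a temporary RNG seed, restoring global state
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

# design matrix of the planar-shear stress in the coefficients:
# sigma = f(lambda) * [1, 2x, 3x^2] %*% c, f = 2(l^2 - l^-2), x = I1 - 3
.yeohDesign <- function(stretch) {
  f <- 2 * (stretch^2 - stretch^-2)
  x <- stretch^2 + 1 + stretch^-2 - 3
  cbind(f, 2 * x * f, 3 * x^2 * f, deparse.level = 0)
}

#' Fit Yeoh coefficients to a stress-stretch curve
#'
#' Minimises the sum of squared differences between
#' [cauchyStressPlanarShear()] and the measured stresses by bounded
#' Levenberg-Marquardt least squares with seeded multi-start initialisation.
#' `c10` is bounded below by `lowerC10` to exclude degenerate zero-stiffness
#' fits. With `enforceStability = TRUE` candidate minima whose response is
#' non-monotone over the curve's stretch range are rejected and the best
#' stable candidate is returned.
#'
#' @param curve A [StressStretchCurve-class].
#' @param enforceStability Reject candidates failing [checkStability()] over
#'   the curve's stretch range (default TRUE).
#' @param seed Integer seed controlling the multi-start initialisation;
#'   results are deterministic given the seed.
#' @param nStarts Number of optimiser starts (default 10).
#' @param lowerC10 Lower bound on `c10` in MPa (default 1e-6).
#' @return A [FitResult-class].
#' @examples
#' lam <- seq(1, 2.16, length.out = 50)
#' gen <- YeohModel(4.98e-2, -6.19e-3, 8.98e-4, "lightly calcified")
#' crv <- StressStretchCurve(lam, cauchyStressPlanarShear(lam, gen))
#' fitYeoh(crv)
#' @export
fitYeoh <- function(curve, enforceStability = TRUE, seed = 1L, nStarts = 10L,
                    lowerC10 = 1e-6) {
  stopifnot(is(curve, "StressStretchCurve"))
  lam <- curve@stretch
  y <- curve@stress
  if (length(lam) < 3L) stop("underdetermined: need at least 3 points")
  A <- .yeohDesign(lam)
  resid <- function(p) drop(A %*% p) - y
  jac <- function(p) A
  # first start: exact linear least-squares solution, clamped to the bound
  start0 <- tryCatch(lm.fit(A, y)$coefficients, error = function(e) c(0, 0, 0))
  start0[!is.finite(start0)] <- 0
  start0[1] <- max(start0[1], lowerC10)
  scale <- max(abs(start0), 1e-3)
  starts <- .withSeed(seed, {
    lapply(seq_len(max(1L, nStarts)), function(k) {
      if (k == 1L) return(start0)
      s <- start0 * (1 + 0.5 * rnorm(3)) + scale * 0.1 * rnorm(3)
      s[1] <- max(s[1], lowerC10)
      s
    })
  })
  fits <- lapply(starts, function(s) {
    out <- tryCatch(
      nls.lm(par = s, lower = c(lowerC10, -Inf, -Inf), fn = resid, jac = jac,
             control = nls.lm.control(maxiter = 500, ftol = 1e-14,
                                      ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(out) || !out$info %in% 1:4) return(NULL)
    list(par = out$par, sse = sum(out$fvec^2), info = out$info)
  })
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits))
    stop("optimiser failed to converge from any of ", nStarts, " starts ",
         "(first start: ", paste(signif(start0, 4), collapse = ", "), ")")
  ord <- order(vapply(fits, `[[`, numeric(1), "sse"))
  rng <- range(lam)
  pick <- NULL
  for (i in ord) {
    m <- YeohModel(fits[[i]]$par[1], fits[[i]]$par[2], fits[[i]]$par[3],
                   label = curve@group)
    st <- checkStability(m, rng)
    if (!enforceStability || st$stable) {
      pick <- list(model = m, sse = fits[[i]]$sse, stable = st$stable)
      break
    }
  }
  if (is.null(pick)) {
    # degenerate null-signal case: the neo-Hookean model at the c10 bound is
    # always stable; accept it when it fits as well as the best minimum
    cand <- c(lowerC10, 0, 0)
    sseCand <- sum((drop(A %*% cand) - y)^2)
    sseBest <- fits[[ord[1]]]$sse
    if (sseCand - sseBest <= 1e-8 * (1 + sum(y^2)))
      pick <- list(model = YeohModel(lowerC10, 0, 0, label = curve@group),
                   sse = sseCand, stable = TRUE)
  }
  if (is.null(pick))
    stop("no stable fit found in ", length(fits), " converged starts over ",
         "stretch range [", signif(rng[1], 4), ", ", signif(rng[2], 4), "]; ",
         "best unstable SSE = ", signif(fits[[ord[1]]]$sse, 4))
  ssTot <- sum((y - mean(y))^2)
  r2 <- if (ssTot <= .Machine$double.eps) NA_real_ else 1 - pick$sse / ssTot
  new("FitResult", model = pick$model, rSquared = r2, stable = pick$stable,
      residualNorm = sqrt(pick$sse))
}

#' Coefficient of determination of a Yeoh model on a curve
#'
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}} computed on stress values about their
#' mean. Errors on a constant-stress curve, where the quantity is undefined.
#'
#' @inheritParams fitYeoh
#' @param model A [YeohModel-class].
#' @return Numeric <= 1.
#' @export
rSquared <- function(curve, model) {
  stopifnot(is(curve, "StressStretchCurve"), is(model, "YeohModel"))
  y <- curve@stress
  ssTot <- sum((y - mean(y))^2)
  if (ssTot <= .Machine$double.eps)
    stop("R^2 undefined for a constant stress curve (zero total variance)")
  pred <- cauchyStressPlanarShear(curve@stretch, model)
  1 - sum((y - pred)^2) / ssTot
}

#' Average the curves of one plaque group
#'
#' Pools all (stretch, stress) points of a group, fits a single polynomial in
#' \eqn{(\lambda - 1)} constrained through the reference state (1, 0), and
#' samples it on a uniform stretch grid truncated at the group's mean ultimate
#' failure stretch.
#'
#' @param curves List of [StressStretchCurve-class] objects, all of one group.
#' @param ultimateStretch Truncation stretch (> 1), typically the group mean
#'   stretch at ultimate mechanically induced failure.
#' @param degree Polynomial degree (default 5; degree 3 visibly under-resolves
#'   the upturn of stiff groups).
#' @param nOut Number of output grid points (default 200).
#' @return A [StressStretchCurve-class] holding the averaged response.
#' @export
averageGroupCurve <- function(curves, ultimateStretch, degree = 5L,
                              nOut = 200L) {
  if (!length(curves)) stop("need at least one curve")
  if (!all(vapply(curves, is, logical(1), "StressStretchCurve")))
    stop("'curves' must be a list of StressStretchCurve objects")
  grp <- unique(vapply(curves, slot, character(1), "group"))
  if (length(grp) != 1L)
    stop("curves from mixed groups: ", paste(grp, collapse = ", "))
  if (!is.finite(ultimateStretch) || ultimateStretch <= 1)
    stop("'ultimateStretch' must be > 1")
  t <- unlist(lapply(curves, function(cv) cv@stretch)) - 1
  y <- unlist(lapply(curves, function(cv) cv@stress))
  X <- outer(t, seq_len(degree), `^`)
  beta <- lm.fit(X, y)$coefficients
  beta[!is.finite(beta)] <- 0
  lamOut <- seq(1, ultimateStretch, length.out = max(3L, nOut))
  yOut <- drop(outer(lamOut - 1, seq_len(degree), `^`) %*% beta)
  yOut[1] <- 0 # exact by the through-origin constraint
  StressStretchCurve(lamOut, yOut, sampleId = paste0("average(", grp, ")"),
                     group = grp)
}

#' Fit one material model per plaque group
#'
#' Applies [fitYeoh()] to one averaged curve per group and assembles the
#' coefficient table (group, C10, C20, C30, R^2) in the layout of the study's
#' material tables.
#'
#' @param groupCurves Named list of [StressStretchCurve-class] objects, one
#'   (averaged) curve per group; names default to the curves' group labels.
#' @inheritParams fitYeoh
#' @return `data.frame` with columns `group`, `c10`, `c20`, `c30`,
#'   `r_squared`, `stable`, `residual_norm`, plus attribute `"fits"` holding
#'   the full [FitResult-class] objects.
#' @export
buildMaterialTable <- function(groupCurves, enforceStability = TRUE,
                               seed = 1L, nStarts = 10L) {
  if (!length(groupCurves)) stop("empty group set")
  if (is.null(names(groupCurves)) || any(!nzchar(names(groupCurves))))
    names(groupCurves) <- vapply(groupCurves, slot, character(1), "group")
  fits <- lapply(groupCurves, fitYeoh, enforceStability = enforceStability,
                 seed = seed, nStarts = nStarts)
  tab <- data.frame(
    group = names(groupCurves),
    c10 = vapply(fits, function(f) f@model@c10, numeric(1)),
    c20 = vapply(fits, function(f) f@model@c20, numeric(1)),
    c30 = vapply(fits, function(f) f@model@c30, numeric(1)),
    r_squared = vapply(fits, slot, numeric(1), "rSquared"),
    stable = vapply(fits, slot, logical(1), "stable"),
    residual_norm = vapply(fits, slot, numeric(1), "residualNorm"),
    row.names = NULL)
  attr(tab, "fits") <- fits
  tab
}
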