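# Independent oracles. Each deliberately re-derives its quantity by a route
# different from the implementation it checks.

# planar-shear Cauchy stress by numeric differentiation of the strain energy
# along the incompressible planar-shear path: sigma = lambda * dPsiHat/dlambda
oracleStressFromEnergy <- function(stretch, model, h = 1e-6) {
  psiHat <- function(l) strainEnergy(firstInvariantPlanarShear(l), model)
  stretch * (psiHat(stretch + h) - psiHat(stretch - h)) / (2 * h)
}

# brute-force stability scan: sign of stress differences on a dense grid
oracleTangentScan <- function(model, range, n = 1e4) {
  grid <- seq(range[1], range[2], length.out = n)
  s <- cauchyStressPlanarShear(grid, model)
  bad <- which(diff(s) <= 0)
  if (length(bad)) list(stable = FALSE, firstViolation = grid[bad[1] + 1])
  else list(stable = TRUE, firstViolation = NA_real_)
}

# classical closed-form solution for the plane-strain incompressible
# neo-Hookean cylinder: with a = ri^2 - Ri^2,
#   sigma_rr(r) = c10 [ ln(R^2/r^2) - a/r^2 ] + const (zero at outer surface)
oracleNeoHookeanProfile <- function(c10, Ri, Ro, ri, r) {
  a <- ri^2 - Ri^2
  ro <- sqrt(Ro^2 + a)
  g <- function(rr) c10 * (log((rr^2 - a) / rr^2) - a / rr^2)
  srr <- g(r) - g(ro)
  R <- sqrt(r^2 - a)
  stt <- srr + 2 * c10 * ((r / R)^2 - (R / r)^2)
  list(srr = srr, stt = stt)
}

# displacement-driven finite-difference solver with penalty incompressibility:
# minimises sum_e [ Psi(I1) + kappa/2 (J - 1)^2 ] Rm dR over nodal deformed
# radii (lumen prescribed, outer traction-free by the natural condition) using
# damped Newton with the analytic tridiagonal Hessian.
fdPenaltySolve <- function(coefAt, Ri, Ro, ri, n = 500, kappa = NULL,
                           maxit = 200) {
  R <- seq(Ri, Ro, length.out = n)
  dR <- diff(R)
  Rm <- 0.5 * (R[-1] + R[-n])
  cm <- t(vapply(Rm, coefAt, numeric(3)))
  if (is.null(kappa)) kappa <- 2e4 * max(cm[, 1])
  energyGrad <- function(r, wantH = FALSE) {
    lt <- 0.5 * (r[-1] + r[-n]) / Rm
    lr <- diff(r) / dR
    J <- lt * lr
    x <- lr^2 + lt^2 + 1 - 3
    p1 <- cm[, 1] + 2 * cm[, 2] * x + 3 * cm[, 3] * x^2
    w <- Rm * dR
    E <- sum((cm[, 1] * x + cm[, 2] * x^2 + cm[, 3] * x^3 +
              kappa / 2 * (J - 1)^2) * w)
    Wt <- (2 * lt * p1 + kappa * (J - 1) * lr) * w
    Wr <- (2 * lr * p1 + kappa * (J - 1) * lt) * w
    at <- 0.5 / Rm
    g <- numeric(n)
    g[1:(n - 1)] <- g[1:(n - 1)] + Wt * at - Wr / dR
    g[2:n] <- g[2:n] + Wt * at + Wr / dR
    out <- list(E = E, g = g)
    if (wantH) {
      p2 <- 2 * cm[, 2] + 6 * cm[, 3] * x
      Wtt <- (2 * p1 + 4 * lt^2 * p2 + kappa * lr^2) * w
      Wrr <- (2 * p1 + 4 * lr^2 * p2 + kappa * lt^2) * w
      Wtr <- (4 * lt * lr * p2 + kappa * (J - 1) + kappa * lt * lr) * w
      out$d <- {
        d <- numeric(n)
        d[1:(n - 1)] <- d[1:(n - 1)] + Wtt * at^2 - 2 * Wtr * at / dR + Wrr / dR^2
        d[2:n] <- d[2:n] + Wtt * at^2 + 2 * Wtr * at / dR + Wrr / dR^2
        d
      }
      out$e <- Wtt * at^2 - Wrr / dR^2
    }
    out
  }
  thomas <- function(d, e, b) {
    m <- length(d)
    cp <- numeric(m - 1)
    dp <- numeric(m)
    cp[1] <- e[1] / d[1]
    dp[1] <- b[1] / d[1]
    for (i in 2:m) {
      den <- d[i] - e[i - 1] * cp[i - 1]
      if (i < m) cp[i] <- e[i] / den
      dp[i] <- (b[i] - e[i - 1] * dp[i - 1]) / den
    }
    x <- numeric(m)
    x[m] <- dp[m]
    for (i in (m - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
    x
  }
  r <- R + (ri - Ri)
  for (it in seq_len(maxit)) {
    eg <- energyGrad(r, wantH = TRUE)
    gf <- eg$g[-1]
    if (max(abs(gf)) < 1e-11 * max(kappa * max(Rm) * max(dR), 1)) break
    step <- thomas(eg$d[-1], eg$e[-1], -gf)
    t <- 1
    repeat {
      rn <- r
      rn[-1] <- r[-1] + t * step
      if (all(diff(rn) > 0) && energyGrad(rn)$E <= eg$E + 1e-12 * abs(eg$E))
        break
      t <- t / 2
      if (t < 1e-10) break
    }
    r[-1] <- r[-1] + t * step
    if (max(abs(t * step)) < 1e-14 * max(r)) break
  }
  lt <- 0.5 * (r[-1] + r[-n]) / Rm
  lr <- diff(r) / dR
  J <- lt * lr
  x <- lr^2 + lt^2 + 1 - 3
  p1 <- cm[, 1] + 2 * cm[, 2] * x + 3 * cm[, 3] * x^2
  pp <- kappa * (J - 1)
  list(rMid = 0.5 * (r[-1] + r[-n]), refMid = Rm,
       stt = lt / J * (2 * lt * p1 + pp * lr),
       srr = lr / J * (2 * lr * p1 + pp * lt),
       J = J, iterations = it)
}
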