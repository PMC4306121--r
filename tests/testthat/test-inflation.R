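test_that("reference configuration follows the stenosis-percentage convention", {
  rr <- referenceConfiguration(defaultGeometry())
  expect_equal(rr[["Ri"]], 0.2975)
  expect_equal(rr[["Rp"]], 2.975)
  expect_equal(rr[["Ro"]], 3.435)
  rrSfa <- referenceConfiguration(defaultGeometry(stenosisReference = "sfa"))
  expect_equal(rrSfa[["Ri"]], 0.3435)
  rrThk <- referenceConfiguration(defaultGeometry(useWallThickness = TRUE))
  expect_equal(rrThk[["Ro"]], 2.975 + 0.48)
  expect_equal(finalLumenRadius(defaultGeometry()), 0.9 * 2.975)
  expect_error(VesselGeometry(6.87, 5.95, 0.48, 10, 90), "<=")
  expect_error(VesselGeometry(5, 6, 0.5, 90, 10), "lumenDiameter")
})

test_that("the radius map conserves every annular area", {
  expect_equal(deformedRadiusMap(c(1, 2, 3), 1, 1), c(1, 2, 3))
  expect_equal(deformedRadiusMap(2.975, 0.2975, 2.6775), 3.99137,
               tolerance = 1e-5)
  set.seed(13)
  Ri <- 0.3; ri <- 2.7
  R <- sort(runif(100, Ri, 3.5))
  r <- deformedRadiusMap(R, Ri, ri)
  expect_equal(r^2 - ri^2, R^2 - Ri^2, tolerance = 1e-12)
  expect_error(deformedRadiusMap(0.1, 0.3, 2.7), ">= Ri")
})

test_that("hoop stress difference matches the energy oracle and coefficient ordering", {
  m <- fixMaterials$heavily
  expect_equal(hoopStressDifference(1, m), 0)
  # identical invariant structure to planar shear, so the same oracle applies
  expect_equal(hoopStressDifference(1.5, m), 0.1190, tolerance = 1e-3)
  expect_equal(hoopStressDifference(1.5, m), oracleStressFromEnergy(1.5, m),
               tolerance = 1e-6)
  aor <- fixMaterials$calcified_aortic
  expect_equal(hoopStressDifference(1.5, aor),
               oracleStressFromEnergy(1.5, aor), tolerance = 1e-6)
  expect_gt(hoopStressDifference(1.5, aor) / hoopStressDifference(1.5, m), 100)
  expect_error(hoopStressDifference(-1, m), "positive")
})

test_that("a no-op revascularisation carries zero stress everywhere", {
  geom <- VesselGeometry(6.87, 5.95, 0.48, 90, 90)
  prof <- solveRevascularisation(geom, fixMaterials$heavily, gridSize = 500)
  expect_lt(max(abs(prof@sigmaRR)), 1e-10)
  expect_lt(max(abs(prof@sigmaTT)), 1e-10)
  expect_lt(max(abs(prof@sigmaZZ)), 1e-10)
})

test_that("every solve satisfies the field equations and boundary conditions", {
  for (g in c("heavily", "calcified_aortic")) {
    prof <- solveRevascularisation(defaultGeometry(), fixMaterials[[g]])
    n <- length(prof@radius)
    expect_lte(abs(prof@sigmaRR[n]), 1e-8)
    expect_lt(equilibriumResidual(prof), 1e-6)
    # sigma_rr continuous across the plaque/wall interface (single field)
    expect_equal(max(abs(diff(prof@sigmaRR[abs(prof@radius - prof@interfaceRadius) < 0.05]))),
                 0, tolerance = 1e-2)
    # sub-annulus area conservation, relative 1e-10
    aDef <- prof@radius^2 - prof@lumenRadius^2
    aRef <- prof@referenceRadius^2 - prof@refLumenRadius^2
    expect_equal(aDef, aRef, tolerance = 1e-10)
    # incompressibility at every node: lr * lt * lz = 1 with lz = 1
    lt <- prof@radius / prof@referenceRadius
    lr <- prof@referenceRadius / prof@radius
    expect_equal(lr * lt, rep(1, n), tolerance = 1e-12)
    expect_equal(prof@sigmaMaxPrincipal,
                 pmax(prof@sigmaRR, prof@sigmaTT, prof@sigmaZZ))
  }
})

test_that("single-layer solve matches the closed-form neo-Hookean cylinder", {
  wall <- defaultWall(0.05)
  geom <- VesselGeometry(6.87, 5.95, 0.48, 90, 10)
  prof <- solveRevascularisation(geom, wall, wall)
  cf <- oracleNeoHookeanProfile(0.05, prof@refLumenRadius,
                                referenceConfiguration(geom)[["Ro"]],
                                prof@lumenRadius, prof@radius)
  scale <- max(abs(cf$stt))
  expect_lt(max(abs(prof@sigmaTT - cf$stt)) / scale, 1e-3)
  expect_lt(max(abs(prof@sigmaRR - cf$srr)) / scale, 1e-3)
})

test_that("solver agrees with the penalty finite-difference oracle", {
  # moderate-stretch two-layer instance: lumen from R = 2 mm to the final
  # stenosis radius, heavy femoral plaque with the default wall
  lumen <- 5.95; sfa <- 6.87
  initPct <- (1 - 2.0 / (lumen / 2)) * 100
  geom <- VesselGeometry(sfa, lumen, 0.48, initPct, 10)
  plaque <- fixMaterials$heavily
  prof <- solveRevascularisation(geom, plaque, defaultWall())
  coefAt <- function(R) {
    m <- if (R <= lumen / 2) plaque else defaultWall()
    unname(yeohCoefficients(m))
  }
  fd <- fdPenaltySolve(coefAt, 2.0, sfa / 2, finalLumenRadius(geom), n = 500)
  expect_lt(max(abs(fd$J - 1)), 1e-3)  # near-incompressible
  sttRef <- stats::approx(prof@radius, prof@sigmaTT, xout = fd$rMid)$y
  rel <- abs(fd$stt - sttRef) / max(abs(sttRef))
  expect_lt(max(rel[-(1:25)]), 0.01)  # within 1% away from the lumen layer
})

test_that("stress at depth interpolates the profile in both conventions", {
  prof <- solveRevascularisation(defaultGeometry(), fixMaterials$heavily)
  expect_equal(stressAtDepth(prof, 0), prof@sigmaMaxPrincipal[1])
  k <- 1500L
  expect_equal(stressAtDepth(prof, prof@depthFromLumen[k]),
               prof@sigmaMaxPrincipal[k])
  # evaluation point for 0.8 mm (deformed) sits at hoop stretch ~1.553
  r <- prof@lumenRadius + 0.8
  R <- sqrt(r^2 - prof@lumenRadius^2 + prof@refLumenRadius^2)
  expect_equal(r / R, 1.553, tolerance = 1e-3)
  # reference convention evaluates deeper into the deformed vessel
  expect_gt(stressAtDepth(prof, 0.8, "reference"),
            stressAtDepth(prof, 0.8, "deformed"))
  expect_error(stressAtDepth(prof, 10), "outside")
})

test_that("material comparison ratios are unit-free and self-consistent", {
  geom <- defaultGeometry()
  m <- fixMaterials$heavily
  same <- compareMaterials(geom, list(a = m, b = m), gridSize = 1000)
  expect_equal(unname(same$ratios["a", "b"]), 1.0)
  # fold change invariant under common scaling of plaque and wall
  s <- 3.7
  scaled <- function(mm) YeohModel(s * mm@c10, s * mm@c20, s * mm@c30)
  base <- compareMaterials(geom, fixMaterials[c("heavily", "calcified_aortic")],
                           wall = defaultWall(0.05), gridSize = 1000)
  scl <- compareMaterials(geom, lapply(fixMaterials[c("heavily", "calcified_aortic")], scaled),
                          wall = defaultWall(s * 0.05), gridSize = 1000)
  expect_equal(unname(scl$ratios[2, 1]), unname(base$ratios[2, 1]),
               tolerance = 1e-10)
  expect_error(compareMaterials(geom, list(only = m)), "at least 2")
})

test_that("stress at a fixed material point grows monotonically with lumen opening", {
  lumen <- 5.95
  Rfix <- 2.0  # material point inside the plaque
  vals <- vapply(seq(60, 10, by = -10), function(finPct) {
    geom <- VesselGeometry(6.87, lumen, 0.48, 90, finPct)
    prof <- solveRevascularisation(geom, fixMaterials$heavily, gridSize = 1500)
    rEval <- deformedRadiusMap(Rfix, prof@refLumenRadius, prof@lumenRadius)
    stats::approx(prof@radius, prof@sigmaMaxPrincipal, xout = rEval)$y
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("unstable materials trigger an extrapolation warning but still solve", {
  soft <- YeohModel(0.01, -10, 0, "softening test material")
  expect_warning(
    prof <- solveRevascularisation(defaultGeometry(), soft, gridSize = 500),
    "non-monotone")
  expect_s4_class(prof, "RadialStressProfile")
})
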