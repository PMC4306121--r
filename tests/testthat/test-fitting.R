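test_that("group averaging reproduces a single curve and ignores duplication", {
  m <- fixMaterials$lightly
  crv <- makeCurve(m, 2.16, group = "lightly")
  avg1 <- averageGroupCurve(list(crv), ultimateStretch = 2.16)
  pred <- stats::approx(avg1@stretch, avg1@stress, xout = crv@stretch)$y
  expect_lt(max(abs(pred - crv@stress)), 1e-3)
  avg2 <- averageGroupCurve(list(crv, crv), ultimateStretch = 2.16)
  expect_equal(avg1@stress, avg2@stress)
  expect_equal(avg1@stress[1], 0)
})

test_that("averaging noiseless synthetic curves recovers the generating stress", {
  for (g in c("lightly", "heavily", "calcified_aortic")) {
    m <- fixMaterials[[g]]
    ult <- fixUltimate[[g]]
    cfg <- synthConfig(g, nSamples = 5, stressNoiseCV = 0, seed = 42)
    curves <- generateStressStretch(cfg, m)
    avg <- averageGroupCurve(curves, ultimateStretch = ult)
    expect_lt(max(abs(avg@stress - cauchyStressPlanarShear(avg@stretch, m))),
              1e-3)
  }
})

test_that("group averaging rejects invalid inputs", {
  crvA <- makeCurve(fixMaterials$lightly, 2.0, group = "lightly")
  crvB <- makeCurve(fixMaterials$heavily, 1.5, group = "heavily")
  expect_error(averageGroupCurve(list(), 2), "at least one")
  expect_error(averageGroupCurve(list(crvA, crvB), 2), "mixed")
  expect_error(averageGroupCurve(list(crvA), 1), "ultimateStretch")
})

test_that("fitYeoh recovers generating coefficients from noiseless curves", {
  # single-term case to near machine precision
  crv <- makeCurve(YeohModel(1), 2)
  fit <- fitYeoh(crv)
  expect_equal(yeohCoefficients(fit@model)[["c10"]], 1, tolerance = 1e-6)
  expect_lt(abs(fit@model@c20), 1e-6)
  expect_lt(abs(fit@model@c30), 1e-6)
  # lightly calcified set on 50 points over [1, 2.16]
  gen <- fixMaterials$lightly
  fit2 <- fitYeoh(makeCurve(gen, 2.16, group = "lightly"))
  expect_equal(unname(yeohCoefficients(fit2@model)),
               unname(yeohCoefficients(gen)), tolerance = 1e-4)
  expect_gt(fit2@rSquared, 0.999999)
  expect_true(fit2@stable)
})

test_that("fitYeoh handles the null signal and is deterministic per seed", {
  lam <- seq(1, 1.8, length.out = 30)
  null <- StressStretchCurve(lam, rep(0, 30))
  fit <- fitYeoh(null)
  expect_lt(fit@model@c10, 1e-5)  # c10 pinned at its lower bound
  expect_lt(abs(fit@model@c20), 1e-5)
  expect_lt(fit@residualNorm, 1e-4)  # ~0 on the MPa scale of the data
  expect_true(is.na(fit@rSquared))
  # determinism on a noisy curve
  noisy <- generateStressStretch(
    synthConfig("moderately", nSamples = 1, seed = 9),
    fixMaterials$moderately)[[1]]
  f1 <- fitYeoh(noisy, seed = 123)
  f2 <- fitYeoh(noisy, seed = 123)
  expect_identical(yeohCoefficients(f1@model), yeohCoefficients(f2@model))
})

test_that("stability-constrained fits pass the stability check on their range", {
  set.seed(31)
  for (k in 1:5) {
    noisy <- generateStressStretch(
      synthConfig("heavily", nSamples = 1, stressNoiseCV = 0.1, seed = k),
      fixMaterials$heavily)[[1]]
    fit <- fitYeoh(noisy, enforceStability = TRUE, seed = k)
    expect_true(checkStability(fit@model, range(noisy@stretch))$stable)
  }
})

test_that("rSquared follows its definition and flags degenerate curves", {
  gen <- fixMaterials$moderately
  crv <- makeCurve(gen, 1.75, group = "moderately")
  expect_equal(rSquared(crv, gen), 1.0)
  # independent recomputation for a mismatched model (2x the coefficients)
  twice <- YeohModel(2 * gen@c10, 2 * gen@c20, 2 * gen@c30)
  pred <- cauchyStressPlanarShear(crv@stretch, twice)
  direct <- 1 - sum((crv@stress - pred)^2) /
    sum((crv@stress - mean(crv@stress))^2)
  expect_equal(rSquared(crv, twice), direct)
  expect_lt(rSquared(crv, twice), 1)
  flat <- StressStretchCurve(seq(1, 1.5, length.out = 10), rep(0, 10))
  expect_error(rSquared(flat, gen), "constant")
})

test_that("a fitted model is locally optimal in R^2 on a perturbation grid", {
  crv <- generateStressStretch(
    synthConfig("lightly", nSamples = 1, stressNoiseCV = 0.05, seed = 4),
    fixMaterials$lightly)[[1]]
  fit <- fitYeoh(crv, enforceStability = FALSE)
  r2fit <- rSquared(crv, fit@model)
  base <- yeohCoefficients(fit@model)
  for (i in 1:3) for (eps in c(-0.02, 0.02)) {
    p <- base
    p[i] <- p[i] * (1 + eps) + 1e-5 * eps
    pert <- YeohModel(max(p[1], 1e-9), p[2], p[3])
    expect_lte(rSquared(crv, pert), r2fit + 1e-12)
  }
})

test_that("buildMaterialTable recovers all six published coefficient sets", {
  curves <- lapply(names(fixMaterials), function(g)
    makeCurve(fixMaterials[[g]], fixUltimate[[g]], group = g))
  names(curves) <- names(fixMaterials)
  tab <- buildMaterialTable(curves)
  expect_equal(nrow(tab), 6L)
  for (g in names(fixMaterials)) {
    row <- tab[tab$group == g, ]
    truth <- yeohCoefficients(fixMaterials[[g]])
    expect_equal(c(row$c10, row$c20, row$c30), unname(truth),
                 tolerance = 1e-3)
    expect_true(row$stable)
  }
  expect_error(buildMaterialTable(list()), "empty")
  one <- buildMaterialTable(curves["heavily"])
  expect_equal(nrow(one), 1L)
})
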