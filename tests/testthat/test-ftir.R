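flatSpectrum <- function(level = 0.2) {
  wn <- seq(700, 4000, by = 2)
  FTIRSpectrum(wn, rep(level, length(wn)), sampleId = "flat")
}

test_that("reference subtraction is pointwise after interpolation", {
  sp <- generateFtirSpectrum(1.8, seed = 2, noiseSD = 0)
  selfSub <- subtractReference(sp, sp)
  expect_equal(selfSub@absorbance, rep(0, length(sp@absorbance)))
  zero <- FTIRSpectrum(sp@wavenumber, rep(0, length(sp@wavenumber)))
  expect_equal(subtractReference(sp, zero)@absorbance, sp@absorbance)
  # coarser-grid reference: equals subtraction of its linear interpolant
  coarseWn <- seq(700, 4000, by = 20)
  ref <- FTIRSpectrum(coarseWn, 0.05 + 1e-5 * coarseWn)
  out <- subtractReference(sp, ref)
  dense <- stats::approx(coarseWn, ref@absorbance, xout = sp@wavenumber)$y
  expect_equal(out@absorbance, sp@absorbance - dense)
  narrow <- FTIRSpectrum(seq(1000, 2000, by = 2), rep(0, 501))
  expect_error(subtractReference(sp, narrow), "cover")
})

test_that("peak area removes the local linear baseline exactly", {
  expect_equal(peakArea(flatSpectrum(), c(900, 1180)), 0)
  # invariance under adding any global linear function of wavenumber
  sp <- generateFtirSpectrum(2.2, seed = 6, noiseSD = 0)
  tilted <- FTIRSpectrum(sp@wavenumber,
                         sp@absorbance + 0.3 - 2e-4 * sp@wavenumber)
  for (band in list(c(900, 1180), c(2845, 2972), c(1710, 1750)))
    expect_equal(peakArea(tilted, band), peakArea(sp, band),
                 tolerance = 1e-10)
  expect_error(peakArea(sp, c(100, 500)), "outside")
})

test_that("peak area converges to closed-form areas of known shapes", {
  # unit-height triangle of width w: area w/2 as the grid refines
  w <- 40
  for (npts in c(500, 5000)) {
    wn <- seq(900, 1300, length.out = npts)
    tri <- pmax(0, 1 - abs(wn - 1100) / (w / 2))
    sp <- FTIRSpectrum(wn, tri)
    expect_equal(peakArea(sp, c(1000, 1200)), w / 2,
                 tolerance = if (npts == 500) 1e-2 else 1e-4)
  }
  # Gaussian band fully inside the band: area A * s * sqrt(2*pi) within 1%
  wn <- seq(700, 4000, by = 2)
  A <- 0.12; s <- 18
  sp <- FTIRSpectrum(wn, A * exp(-0.5 * ((wn - 1030) / s)^2))
  expect_equal(peakArea(sp, c(900, 1180)), A * s * sqrt(2 * pi),
               tolerance = 0.01)
})

test_that("Ca:Li ratio recovers generator ground truth", {
  sp <- generateFtirSpectrum(2.0, seed = 1, noiseSD = 0)
  expect_equal(caLiRatio(sp), 2.0, tolerance = 0.02)
  # no phosphate band: ratio ~ 0
  wn <- seq(700, 4000, by = 2)
  lipidOnly <- FTIRSpectrum(wn, 0.1 * exp(-0.5 * ((wn - 2925) / 9)^2))
  expect_lt(caLiRatio(lipidOnly), 1e-6)
  expect_error(caLiRatio(FTIRSpectrum(wn, rep(0, length(wn)))), "lipid")
})

test_that("classification follows the published intervals with half-open bounds", {
  expect_equal(classifyCaLi(1.2), "lightly")
  expect_equal(classifyCaLi(2.5), "heavily")
  expect_equal(classifyCaLi(1.5), "moderately")  # boundary joins upper class
  expect_equal(classifyCaLi(2), "heavily")
  expect_equal(classifyCaLi(c(0.5, 1, 3, 10)),
               rep("unclassified", 4))
  expect_error(classifyCaLi(0), "positive")
  # monotone step function: higher ratio never maps to a lighter class
  rank <- c(unclassified = 0, lightly = 1, moderately = 2, heavily = 3)
  ratios <- seq(1.01, 2.99, by = 0.01)
  cls <- rank[classifyCaLi(ratios)]
  expect_true(all(diff(cls) >= 0))
})

test_that("spectra round-trip through file reading", {
  sp <- generateFtirSpectrum(1.3, seed = 8, noiseSD = 0.001)
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(wavenumber = sp@wavenumber, abs = sp@absorbance),
              path, row.names = FALSE, sep = "\t")
  rd <- readSpectrum(path)
  expect_equal(rd@wavenumber, sp@wavenumber)
  expect_equal(rd@absorbance, sp@absorbance, tolerance = 1e-12)
  tab <- classifySpectra(list(sp, generateFtirSpectrum(2.4, seed = 9)))
  expect_equal(tab$group, c("lightly", "heavily"))
  out <- withr::local_tempfile(fileext = ".tsv")
  writeClassification(tab, out)
  expect_true(file.exists(out))
})
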