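## FTIR peak-area classification. Areas are trapezoidal integrals over fixed
## wavenumber bands after removing a local linear baseline joining the band
## endpoints, so any global linear-in-wavenumber background cancels exactly.

.defaultBands <- function() {
  list(lipid_ch2 = c(2845, 2972),  # CH2 stretch doublet
       lipid_ester = c(1710, 1750),  # carbonyl ester around 1730 cm^-1
       phosphate = c(900, 1180))  # nu3 phosphate (calcification)
}

#' Read a two-column spectrum file
#'
#' Reads delimited text with wavenumber (cm^-1) and absorbance columns
#' (whitespace, comma or tab separated; `#` comments and an optional header
#' line are skipped).
#'
#' @param path File path.
#' @param sampleId Identifier; defaults to the file name.
#' @return An [FTIRSpectrum-class].
#' @export
readSpectrum <- function(path, sampleId = basename(path)) {
  if (!file.exists(path)) stop("spectrum file not found: ", path)
  first <- readLines(path, n = 1L)
  hasHeader <- !grepl("^\\s*#", first) &&
    is.na(suppressWarnings(as.numeric(strsplit(trimws(first), "[,;\t ]+")[[1]][1])))
  tab <- read.table(path, header = hasHeader, sep = "", comment.char = "#",
                    blank.lines.skip = TRUE)
  if (ncol(tab) == 1L)  # comma-separated fallback
    tab <- read.table(path, header = hasHeader, sep = ",", comment.char = "#")
  if (ncol(tab) < 2L) stop("expected two columns (wavenumber, absorbance)")
  FTIRSpectrum(tab[[1]], tab[[2]], sampleId = sampleId)
}

#' Subtract a reference spectrum
#'
#' Subtracts a reference (e.g. water) spectrum pointwise after linearly
#' interpolating it onto the sample's wavenumber grid. The reference must
#' cover the sample's full range.
#'
#' @param spectrum,reference [FTIRSpectrum-class] objects.
#' @return An [FTIRSpectrum-class] on the sample's grid.
#' @export
subtractReference <- function(spectrum, reference) {
  stopifnot(is(spectrum, "FTIRSpectrum"), is(reference, "FTIRSpectrum"))
  rs <- range(spectrum@wavenumber)
  rr <- range(reference@wavenumber)
  if (rr[1] > rs[1] + 1e-9 || rr[2] < rs[2] - 1e-9)
    stop(sprintf(
      "reference range (%.1f-%.1f) does not cover the spectrum (%.1f-%.1f)",
      rr[1], rr[2], rs[1], rs[2]))
  ref <- approx(reference@wavenumber, reference@absorbance,
                xout = spectrum@wavenumber)$y
  FTIRSpectrum(spectrum@wavenumber, spectrum@absorbance - ref,
               sampleId = spectrum@sampleId, meta = spectrum@meta)
}

#' Baseline-corrected peak area over a wavenumber band
#'
#' Resamples the spectrum onto a uniform grid over the band (step = 2 cm^-1,
#' the acquisition resolution, or the native spacing when finer), subtracts
#' the linear baseline joining the band endpoints, and integrates by the
#' trapezoidal rule. Negative net areas are clipped at zero.
#'
#' @param spectrum An [FTIRSpectrum-class].
#' @param band Interval `c(lo, hi)` in cm^-1, inside the spectrum's range.
#' @return Non-negative area (absorbance * cm^-1).
#' @export
peakArea <- function(spectrum, band) {
  stopifnot(is(spectrum, "FTIRSpectrum"))
  if (length(band) != 2L || any(!is.finite(band)))
    stop("'band' must be a finite interval c(lo, hi)")
  band <- sort(band)
  rng <- range(spectrum@wavenumber)
  if (band[1] < rng[1] - 1e-9 || band[2] > rng[2] + 1e-9)
    stop(sprintf("band %.1f-%.1f outside spectrum range %.1f-%.1f",
                 band[1], band[2], rng[1], rng[2]))
  step <- min(2, stats::median(abs(diff(spectrum@wavenumber))))
  grid <- seq(band[1], band[2],
              length.out = max(2L, ceiling(diff(band) / step) + 1L))
  y <- approx(spectrum@wavenumber, spectrum@absorbance, xout = grid)$y
  baseline <- y[1] + (y[length(y)] - y[1]) *
    (grid - grid[1]) / (grid[length(grid)] - grid[1])
  d <- y - baseline
  area <- sum(0.5 * (d[-1] + d[-length(d)]) * diff(grid))
  max(area, 0)
}

#' Calcification-to-lipid (Ca:Li) peak-area ratio
#'
#' Ratio of the phosphate peak area (1180-900 cm^-1) to the lipid peak area,
#' where lipid is the CH2 stretch band (2972-2845 cm^-1) plus the carbonyl
#' ester band around 1730 cm^-1. The ester band is not always detectable; it
#' is included whenever its baseline-corrected area is positive (and with
#' areas clipped at zero this amounts to always adding it).
#'
#' @param spectrum An [FTIRSpectrum-class] covering all three bands.
#' @param bands Named list with elements `lipid_ch2`, `lipid_ester`,
#'   `phosphate`, each an interval in cm^-1. Defaults: 2845-2972, 1710-1750,
#'   900-1180.
#' @return Positive Ca:Li ratio (dimensionless).
#' @export
caLiRatio <- function(spectrum, bands = .defaultBands()) {
  stopifnot(is(spectrum, "FTIRSpectrum"))
  ca <- peakArea(spectrum, bands$phosphate)
  li <- peakArea(spectrum, bands$lipid_ch2) +
    peakArea(spectrum, bands$lipid_ester)
  if (li <= 0)
    stop("zero lipid peak area: Ca:Li ratio undefined for '",
         spectrum@sampleId, "'")
  ca / li
}

#' Classify a Ca:Li ratio into a calcification grade
#'
#' Grades: lightly calcified for ratios in (1, 1.5), moderately calcified in
#' \[1.5, 2), heavily calcified in \[2, 3). Interior boundaries follow the
#' half-open convention (a boundary ratio joins the upper class); ratios <= 1
#' or >= 3 are `"unclassified"`.
#'
#' @param ratio Positive Ca:Li ratio(s).
#' @return Character vector of group labels.
#' @examples
#' classifyCaLi(c(1.2, 1.5, 2.5))
#' @export
classifyCaLi <- function(ratio) {
  if (!length(ratio) || any(!is.finite(ratio)) || any(ratio <= 0))
    stop("'ratio' must be positive and finite")
  out <- rep("unclassified", length(ratio))
  out[ratio > 1 & ratio < 1.5] <- "lightly"
  out[ratio >= 1.5 & ratio < 2] <- "moderately"
  out[ratio >= 2 & ratio < 3] <- "heavily"
  out
}

#' Classify a set of spectra
#'
#' @param spectra List of [FTIRSpectrum-class] objects.
#' @param bands See [caLiRatio()].
#' @return `data.frame` with `sample_id`, `ca_li_ratio`, `group`.
#' @export
classifySpectra <- function(spectra, bands = .defaultBands()) {
  stopifnot(length(spectra) >= 1L)
  ratios <- vapply(spectra, caLiRatio, numeric(1), bands = bands)
  data.frame(sample_id = vapply(spectra, slot, character(1), "sampleId"),
             ca_li_ratio = ratios, group = classifyCaLi(ratios),
             row.names = NULL)
}

#' Write a classification table
#'
#' @param classification Output of [classifySpectra()].
#' @param path Output file (tab-separated).
#' @return `path`, invisibly.
#' @export
writeClassification <- function(classification, path) {
  write.table(classification, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
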