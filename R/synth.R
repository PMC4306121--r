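## Synthetic data generators. These emulate the statistical structure of the
## study's inputs: group-specific Yeoh-shaped planar-shear curves truncated
## at a sampled ultimate failure stretch with multiplicative (CV-based)
## stress noise, and ATR-FTIR spectra built from Gaussian absorbance bands
## whose closed-form areas realise a prescribed Ca:Li ratio. All generators
## are bit-reproducible given a seed and store their ground truth as
## metadata so recovery tests never re-derive it.

#' Synthetic stress-stretch generator configuration
#'
#' @param group Plaque group label (see [plaqueGroups()]).
#' @param nSamples Number of curves (>= 1).
#' @param nPoints Points per curve (>= 3; default 50).
#' @param stressNoiseCV Coefficient of variation of the multiplicative
#'   Gaussian stress noise (>= 0; default 0.05, the scatter scale of
#'   soft-tissue testing).
#' @param failureStretchMean,failureStretchSD Ultimate failure stretch
#'   distribution; defaults come from the group's [failureCriteria()] entry.
#' @param seed Integer seed.
#' @return Validated configuration list of class `"synthConfig"`.
#' @export
synthConfig <- function(group, nSamples = 1L, nPoints = 50L,
                        stressNoiseCV = 0.05, failureStretchMean = NULL,
                        failureStretchSD = NULL, seed = 1L) {
  crit <- failureCriteria()[[group]]
  if (is.null(failureStretchMean))
    failureStretchMean <- if (!is.null(crit)) crit@stretchMean else
      stop("no default failure stretch for group '", group, "'")
  if (is.null(failureStretchSD))
    failureStretchSD <- if (!is.null(crit) && is.finite(crit@stretchSD))
      crit@stretchSD else 0
  cfg <- list(group = group, nSamples = as.integer(nSamples),
              nPoints = as.integer(nPoints),
              stressNoiseCV = as.numeric(stressNoiseCV),
              failureStretchMean = as.numeric(failureStretchMean),
              failureStretchSD = as.numeric(failureStretchSD),
              seed = as.integer(seed))
  if (!cfg$group %in% plaqueGroups()) stop("unknown group '", group, "'")
  if (cfg$nSamples < 1L) stop("'nSamples' must be >= 1")
  if (cfg$nPoints < 3L) stop("'nPoints' must be >= 3")
  if (cfg$stressNoiseCV < 0) stop("'stressNoiseCV' must be >= 0")
  if (cfg$failureStretchMean <= 1) stop("failure stretch mean must be > 1")
  class(cfg) <- "synthConfig"
  cfg
}

#' Generate synthetic planar-shear curves
#'
#' Each curve is sampled on a uniform stretch grid from 1 to a per-sample
#' ultimate failure stretch drawn from a normal distribution truncated above
#' 1.05, with stresses from [cauchyStressPlanarShear()] perturbed by
#' multiplicative Gaussian noise of the configured CV. Deterministic per
#' seed; the generating model and failure stretches are attached as the
#' `"truth"` attribute.
#'
#' @param config A [synthConfig()] object.
#' @param model Generating [YeohModel-class].
#' @return List of [StressStretchCurve-class] objects.
#' @export
generateStressStretch <- function(config, model) {
  stopifnot(inherits(config, "synthConfig"), is(model, "YeohModel"))
  curves <- .withSeed(config$seed, {
    lapply(seq_len(config$nSamples), function(k) {
      lamFail <- if (config$failureStretchSD > 0) {
        repeat {
          v <- rnorm(1, config$failureStretchMean, config$failureStretchSD)
          if (v > 1.05) break
        }
        v
      } else max(config$failureStretchMean, 1.05)
      lam <- seq(1, lamFail, length.out = config$nPoints)
      sig <- cauchyStressPlanarShear(lam, model)
      if (config$stressNoiseCV > 0)
        sig <- sig * (1 + rnorm(length(sig), 0, config$stressNoiseCV))
      StressStretchCurve(lam, sig,
                         sampleId = sprintf("%s_synth_%02d", config$group, k),
                         group = config$group)
    })
  })
  attr(curves, "truth") <- list(
    model = model,
    failureStretch = vapply(curves, function(cv) max(cv@stretch), numeric(1)),
    config = config)
  curves
}

# closed-form area of a Gaussian band: amplitude * sigma * sqrt(2*pi)
.gaussArea <- function(amplitude, sigma) amplitude * sigma * sqrt(2 * pi)

.gauss <- function(x, centre, sigma) exp(-0.5 * ((x - centre) / sigma)^2)

#' Generate a synthetic ATR-FTIR spectrum with a prescribed Ca:Li ratio
#'
#' Builds a spectrum on a 2 cm^-1 grid over 700-4000 cm^-1 from Gaussian
#' absorbance bands: a CH2 stretch doublet (2925 and 2855 cm^-1), a carbonyl
#' ester band (1730 cm^-1) and a broad phosphate band (1030 cm^-1) whose
#' closed-form areas give exactly the target Ca:Li ratio, plus a smooth
#' baseline (linear trend and a very broad background bump) and additive
#' Gaussian noise. The generating areas are stored in the `meta` slot.
#'
#' @param targetCaLi Target Ca:Li ratio (> 0).
#' @param seed Integer seed.
#' @param noiseSD Additive absorbance noise SD (default 0.001, a typical
#'   16-scan ATR noise floor).
#' @param sampleId Identifier.
#' @return An [FTIRSpectrum-class] with `meta` holding `targetCaLi`,
#'   `lipidArea`, `phosphateArea`.
#' @export
generateFtirSpectrum <- function(targetCaLi, seed = 1L, noiseSD = 0.001,
                                 sampleId = sprintf("synth_cali_%.3g", targetCaLi)) {
  if (!is.finite(targetCaLi) || targetCaLi <= 0)
    stop("'targetCaLi' must be positive")
  wn <- seq(700, 4000, by = 2)
  # lipid bands: total closed-form area 4 (absorbance * cm^-1)
  bands <- list(
    list(centre = 2925, sigma = 9, area = 2.0),   # CH2 asymmetric stretch
    list(centre = 2855, sigma = 3, area = 1.0),   # CH2 symmetric stretch
    list(centre = 1730, sigma = 6, area = 1.0),   # ester carbonyl
    list(centre = 1030, sigma = 30, area = 4.0 * targetCaLi))  # nu3 phosphate
  ab <- 0.01 + 4e-6 * (wn - 700) + 0.02 * .gauss(wn, 1900, 800)  # baseline
  for (b in bands)
    ab <- ab + b$area / (b$sigma * sqrt(2 * pi)) * .gauss(wn, b$centre, b$sigma)
  if (noiseSD > 0)
    ab <- .withSeed(seed, ab + rnorm(length(ab), 0, noiseSD))
  FTIRSpectrum(wn, ab, sampleId = sampleId,
               meta = list(targetCaLi = targetCaLi, lipidArea = 4.0,
                           phosphateArea = 4.0 * targetCaLi))
}

#' Generate a labelled synthetic cohort of curves and spectra
#'
#' Emulates a study cohort: for each femoral calcification class the
#' requested number of samples is generated, each with a planar-shear curve
#' (from that group's published coefficients and failure statistics) and an
#' FTIR spectrum whose target Ca:Li ratio is drawn uniformly within the
#' class interval at a 0.1 margin from the class boundaries.
#'
#' @param counts Numeric vector of per-class sample counts, named or in the
#'   order `lightly`, `moderately`, `heavily`; zeros allowed.
#' @param seed Integer seed.
#' @param stressNoiseCV Stress noise CV for the curves (default 0.05).
#' @param noiseSD Absorbance noise SD for the spectra (default 0.001).
#' @return List with `curves`, `spectra` and `labels` (data.frame of
#'   `sample_id`, `group`, `true_ca_li`).
#' @export
generateCohort <- function(counts, seed = 1L, stressNoiseCV = 0.05,
                           noiseSD = 0.001) {
  classes <- c("lightly", "moderately", "heavily")
  if (is.null(names(counts))) names(counts) <- classes[seq_along(counts)]
  if (!all(names(counts) %in% classes))
    stop("counts must be named among: ", paste(classes, collapse = ", "))
  if (any(counts < 0)) stop("counts must be >= 0")
  intervals <- list(lightly = c(1.1, 1.4), moderately = c(1.6, 1.9),
                    heavily = c(2.1, 2.9))
  mats <- femoralMaterials()
  curves <- list(); spectra <- list(); labels <- NULL
  targets <- .withSeed(seed, {
    lapply(names(counts), function(g)
      runif(counts[[g]], intervals[[g]][1], intervals[[g]][2]))
  })
  names(targets) <- names(counts)
  idx <- 0L
  for (g in names(counts)) {
    n <- as.integer(counts[[g]])
    if (n == 0L) next
    cfg <- synthConfig(g, nSamples = n, stressNoiseCV = stressNoiseCV,
                       seed = seed + match(g, classes))
    gc <- generateStressStretch(cfg, mats[[g]])
    for (k in seq_len(n)) {
      idx <- idx + 1L
      id <- sprintf("cohort_%02d", idx)
      cv <- gc[[k]]; cv@sampleId <- id
      curves[[id]] <- cv
      spectra[[id]] <- generateFtirSpectrum(targets[[g]][k],
                                            seed = seed + 1000L + idx,
                                            noiseSD = noiseSD, sampleId = id)
      labels <- rbind(labels, data.frame(sample_id = id, group = g,
                                         true_ca_li = targets[[g]][k]))
    }
  }
  list(curves = curves, spectra = spectra,
       labels = if (is.null(labels))
         data.frame(sample_id = character(), group = character(),
                    true_ca_li = numeric())
       else labels)
}
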