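## Failure assessment: computed stress/stretch states versus the ultimate
## mechanically induced failure criteria of each plaque group. Comparison is
## against the group mean; exceedance is strict, so a state exactly at the
## mean is (by documented tie-break) not failed.

#' Assess a stress/stretch state against a failure criterion
#'
#' @param stress Maximum principal Cauchy stress (MPa), >= 0.
#' @param stretch Stretch ratio at the same point, >= 0. May be `NA` when
#'   `mode = "stress"`.
#' @param criterion A [FailureCriterion-class].
#' @param mode Which quantity must exceed its ultimate mean: `"stress"`
#'   (default), `"stretch"`, or `"either"`.
#' @return List with `failed` (logical), `stressMargin` (stress - ultimate
#'   stress, MPa) and `stretchMargin` (stretch - ultimate stretch).
#' @examples
#' crit <- failureCriteria()$heavily
#' exceedsFailure(0.10, NA, crit)  # below the 0.16 MPa ultimate stress
#' @export
exceedsFailure <- function(stress, stretch = NA_real_, criterion,
                           mode = c("stress", "stretch", "either")) {
  stopifnot(is(criterion, "FailureCriterion"))
  mode <- match.arg(mode)
  if (!is.finite(stress) || stress < 0) stop("'stress' must be >= 0")
  if (!is.na(stretch) && stretch < 0) stop("'stretch' must be >= 0")
  if (mode != "stress" && is.na(stretch))
    stop("'stretch' required for mode '", mode, "'")
  overStress <- stress > criterion@stressMean
  overStretch <- if (is.na(stretch)) NA else stretch > criterion@stretchMean
  failed <- switch(mode,
                   stress = overStress,
                   stretch = overStretch,
                   either = isTRUE(overStress) || isTRUE(overStretch))
  list(failed = failed,
       stressMargin = stress - criterion@stressMean,
       stretchMargin = if (is.na(stretch)) NA_real_
                       else stretch - criterion@stretchMean)
}

# femoral groups carry no suffix; aortic groups end in "_aortic"
.tissueOrigin <- function(group) {
  ifelse(grepl("aortic", group), "aortic", "femoral")
}

#' Failure report across material models
#'
#' Compares the maximum principal stress at a stated depth, one value per
#' plaque material model, against each group's ultimate failure criterion and
#' summarises failures by tissue origin (femoral vs aortic).
#'
#' @param stresses Named numeric vector of maximum principal stresses (MPa)
#'   at the evaluation depth; names are group labels.
#' @param criteria Named list of [FailureCriterion-class] objects covering
#'   every name in `stresses` (default [failureCriteria()]).
#' @param mode See [exceedsFailure()].
#' @return List with `table` (per-group rows: group, stress, ultimate stress,
#'   margin, failed, origin) and `summary` (failures per tissue origin).
#' @export
failureReport <- function(stresses, criteria = failureCriteria(),
                          mode = c("stress", "stretch", "either")) {
  mode <- match.arg(mode)
  if (!length(stresses) || is.null(names(stresses)))
    stop("'stresses' must be a named vector of stresses at depth")
  missing <- setdiff(names(stresses), names(criteria))
  if (length(missing))
    stop("no failure criterion for group(s): ", paste(missing, collapse = ", "))
  rows <- lapply(names(stresses), function(g) {
    res <- exceedsFailure(stresses[[g]], NA_real_, criteria[[g]], mode = "stress")
    data.frame(group = g, sigma_max_principal_MPa = stresses[[g]],
               ultimate_stress_MPa = criteria[[g]]@stressMean,
               stress_margin_MPa = res$stressMargin, failed = res$failed,
               origin = .tissueOrigin(g))
  })
  tab <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(tab, tab$origin), function(d)
    data.frame(origin = d$origin[1], n_failed = sum(d$failed),
               n_total = nrow(d))))
  rownames(summ) <- NULL
  list(table = tab, summary = summ)
}
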