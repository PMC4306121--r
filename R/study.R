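## End-to-end study orchestration: fit (or load) the material table, solve
## the six revascularisation simulations, compare stresses at the depth of
## interest, assess failure, and write a sensitivity appendix spanning the
## undetermined modelling conventions (wall stiffness, stenosis-percentage
## reference, depth convention).

.defaultStudyConfig <- function() {
  list(
    geometry = list(sfa_diameter_mm = 6.87, lumen_diameter_mm = 5.95,
                    wall_thickness_mm = 0.48, initial_stenosis_pct = 90,
                    final_stenosis_pct = 10),
    stenosis_reference = "healthy_lumen",
    use_wall_thickness = FALSE,
    depth_mm = 0.8,
    depth_convention = "deformed",
    wall = list(type = "neo_hookean", c10 = 0.05),
    materials = "printed",
    grid_size = 4000,
    sensitivity_wall_c10 = c(0.01, 0.05, 0.2),
    seed = 1,
    out_dir = "plaqueMech-study")
}

#' Validate (and complete) a study configuration
#'
#' Accepts a configuration as an R list or a path to a YAML file, injects
#' defaults for all missing fields, and validates every field, collecting
#' all problems into a single itemised error.
#'
#' Recognised fields: `geometry` (`sfa_diameter_mm`, `lumen_diameter_mm`,
#' `wall_thickness_mm`, `initial_stenosis_pct`, `final_stenosis_pct`),
#' `stenosis_reference` (`"healthy_lumen"`/`"sfa"`), `use_wall_thickness`,
#' `depth_mm`, `depth_convention` (`"deformed"`/`"reference"`), `wall`
#' (`type` one of `"neo_hookean"` with `c10`, `"plaque"`, `"rigid"`),
#' `materials` (`"printed"` or a named list of curve-file paths per group),
#' `grid_size`, `sensitivity_wall_c10`, `seed`, `out_dir`.
#'
#' @param config List or YAML file path; `NULL` gives the full default.
#' @return Completed configuration list (invisibly validated), with the
#'   derived [VesselGeometry-class] attached as `$geometryObject`.
#' @export
validateStudyConfig <- function(config = NULL) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(config)) config <- list()
  if (!is.list(config)) stop("'config' must be a list or a YAML file path")
  def <- .defaultStudyConfig()
  unknown <- setdiff(names(config), names(def))
  cfg <- utils::modifyList(def, config[intersect(names(config), names(def))])
  errs <- character()
  if (length(unknown))
    errs <- c(errs, paste0("unknown field(s): ", paste(unknown, collapse = ", ")))
  g <- cfg$geometry
  for (f in c("sfa_diameter_mm", "lumen_diameter_mm", "wall_thickness_mm",
              "initial_stenosis_pct", "final_stenosis_pct"))
    if (!is.numeric(g[[f]]) || !is.finite(g[[f]]))
      errs <- c(errs, paste0("geometry$", f, " must be a finite number"))
  if (is.numeric(g$final_stenosis_pct) && is.numeric(g$initial_stenosis_pct) &&
      g$final_stenosis_pct >= g$initial_stenosis_pct)
    errs <- c(errs, "final stenosis must be below the initial stenosis")
  if (!cfg$stenosis_reference %in% c("healthy_lumen", "sfa"))
    errs <- c(errs, paste0("stenosis_reference must be 'healthy_lumen' or 'sfa', got '",
                           cfg$stenosis_reference, "'"))
  if (!cfg$depth_convention %in% c("deformed", "reference"))
    errs <- c(errs, "depth_convention must be 'deformed' or 'reference'")
  if (!is.numeric(cfg$depth_mm) || cfg$depth_mm <= 0)
    errs <- c(errs, "depth_mm must be > 0")
  if (!is.numeric(cfg$grid_size) || cfg$grid_size < 100)
    errs <- c(errs, "grid_size must be >= 100")
  wallTypes <- c("neo_hookean", "plaque", "rigid")
  if (!is.list(cfg$wall) || is.null(cfg$wall$type) ||
      !cfg$wall$type %in% wallTypes)
    errs <- c(errs, paste0("wall$type must be one of: ",
                           paste(wallTypes, collapse = ", ")))
  else if (cfg$wall$type == "neo_hookean" &&
           (!is.numeric(cfg$wall$c10) || cfg$wall$c10 <= 0))
    errs <- c(errs, "wall$c10 must be > 0 for a neo-Hookean wall")
  if (is.list(cfg$materials)) {
    bad <- Filter(function(p) !file.exists(p), unlist(cfg$materials))
    if (length(bad))
      errs <- c(errs, paste0("missing material curve file(s): ",
                             paste(bad, collapse = ", ")))
  } else if (!identical(cfg$materials, "printed")) {
    errs <- c(errs, "materials must be 'printed' or a named list of curve files")
  }
  geomObj <- NULL
  if (!length(errs)) {
    geomObj <- tryCatch(
      VesselGeometry(g$sfa_diameter_mm, g$lumen_diameter_mm,
                     g$wall_thickness_mm, g$initial_stenosis_pct,
                     g$final_stenosis_pct, cfg$stenosis_reference,
                     cfg$use_wall_thickness),
      error = function(e) { errs <<- c(errs, conditionMessage(e)); NULL })
    if (!is.null(geomObj) && !is.null(cfg$depth_mm)) {
      rr <- referenceConfiguration(geomObj)
      ro <- deformedRadiusMap(rr[["Ro"]], rr[["Ri"]], finalLumenRadius(geomObj))
      if (cfg$depth_mm > ro - finalLumenRadius(geomObj))
        errs <- c(errs, sprintf(
          "depth_mm = %g exceeds the deformed vessel thickness (%.3f mm)",
          cfg$depth_mm, ro - finalLumenRadius(geomObj)))
    }
  }
  if (length(errs))
    stop("invalid study configuration:\n", paste0("  - ", errs, collapse = "\n"))
  cfg$geometryObject <- geomObj
  cfg
}

# resolve a wall specification to a YeohModel, given the plaque model
.resolveWall <- function(wall, plaque) {
  switch(wall$type,
         neo_hookean = defaultWall(wall$c10),
         plaque = plaque,
         rigid = YeohModel(100, 0, 0, "near-rigid outer wall"))
}

# material table: printed coefficient sets, or fits to user curve files
.resolveMaterials <- function(cfg) {
  if (identical(cfg$materials, "printed")) return(plaqueMaterials())
  fitted <- lapply(names(cfg$materials), function(g) {
    tab <- read.table(cfg$materials[[g]], header = TRUE)
    crv <- StressStretchCurve(tab[[1]], tab[[2]], sampleId = g, group = g)
    fitYeoh(crv, seed = cfg$seed)@model
  })
  names(fitted) <- names(cfg$materials)
  fitted
}

#' Run the full material-model comparison study
#'
#' Executes the pipeline: resolve the material table (printed coefficients or
#' fits to supplied curves), solve the revascularisation for every plaque
#' material under the shared wall model, extract the maximum principal stress
#' at the configured depth, form all pairwise fold changes, assess each group
#' against its ultimate failure criterion, and sweep the sensitivity grid
#' (both stenosis references x both depth conventions x the configured wall
#' stiffnesses). Writes delimited tables plus a JSON run manifest to
#' `out_dir`.
#'
#' Outputs: `material_table.csv`, `profile_<group>.csv` (one per material),
#' `fold_changes.csv`, `failure_report.csv`, `sensitivity.csv`,
#' `manifest.json`.
#'
#' @param config See [validateStudyConfig()]; defaults used when `NULL`.
#' @param outDir Output directory (default from the config).
#' @return Invisibly, a list with `materials`, `profiles`, `stresses`,
#'   `foldChanges`, `failure`, `sensitivity`, `headlineRatio`.
#' @export
runStudy <- function(config = NULL, outDir = NULL) {
  cfg <- validateStudyConfig(config)
  if (is.null(outDir)) outDir <- cfg$out_dir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  materials <- .resolveMaterials(cfg)
  geom <- cfg$geometryObject
  solveOne <- function(m, geometry = geom, gridSize = cfg$grid_size,
                       wallSpec = cfg$wall)
    solveRevascularisation(geometry, m, .resolveWall(wallSpec, m),
                           gridSize = gridSize)
  profiles <- lapply(materials, solveOne)
  stresses <- vapply(profiles, stressAtDepth, numeric(1),
                     depth = cfg$depth_mm, convention = cfg$depth_convention)
  ratios <- outer(stresses, stresses, `/`)
  dimnames(ratios) <- list(names(materials), names(materials))
  headline <- if (all(c("calcified_aortic", "heavily") %in% names(stresses)))
    unname(stresses[["calcified_aortic"]] / stresses[["heavily"]])
  else NA_real_
  fail <- failureReport(stresses)
  # sensitivity appendix over the undetermined conventions
  sens <- NULL
  aMat <- materials[["calcified_aortic"]]; fMat <- materials[["heavily"]]
  if (!is.null(aMat) && !is.null(fMat)) {
    for (ref in c("healthy_lumen", "sfa"))
      for (conv in c("deformed", "reference"))
        for (w in cfg$sensitivity_wall_c10) {
          gg <- VesselGeometry(cfg$geometry$sfa_diameter_mm,
                               cfg$geometry$lumen_diameter_mm,
                               cfg$geometry$wall_thickness_mm,
                               cfg$geometry$initial_stenosis_pct,
                               cfg$geometry$final_stenosis_pct,
                               ref, cfg$use_wall_thickness)
          ws <- list(type = "neo_hookean", c10 = w)
          sF <- stressAtDepth(solveOne(fMat, gg, wallSpec = ws),
                              cfg$depth_mm, conv)
          sA <- stressAtDepth(solveOne(aMat, gg, wallSpec = ws),
                              cfg$depth_mm, conv)
          sens <- rbind(sens, data.frame(
            stenosis_reference = ref, depth_convention = conv,
            wall_c10_MPa = w, femoral_heavily_MPa = sF,
            aortic_calcified_MPa = sA, fold_change = sA / sF))
        }
  }
  # ---- write outputs
  matTab <- data.frame(
    group = names(materials),
    c10 = vapply(materials, slot, numeric(1), "c10"),
    c20 = vapply(materials, slot, numeric(1), "c20"),
    c30 = vapply(materials, slot, numeric(1), "c30"), row.names = NULL)
  write.csv(matTab, file.path(outDir, "material_table.csv"), row.names = FALSE)
  for (g in names(profiles))
    write.csv(as.data.frame(profiles[[g]]),
              file.path(outDir, paste0("profile_", g, ".csv")),
              row.names = FALSE)
  foldTab <- data.frame(
    material = rep(rownames(ratios), ncol(ratios)),
    versus = rep(colnames(ratios), each = nrow(ratios)),
    fold_change = as.vector(ratios))
  write.csv(foldTab, file.path(outDir, "fold_changes.csv"), row.names = FALSE)
  write.csv(fail$table, file.path(outDir, "failure_report.csv"),
            row.names = FALSE)
  if (!is.null(sens))
    write.csv(sens, file.path(outDir, "sensitivity.csv"), row.names = FALSE)
  manifest <- list(
    package = "plaqueMech",
    version = as.character(packageVersion("plaqueMech")),
    seed = cfg$seed,
    depth_mm = cfg$depth_mm,
    depth_convention = cfg$depth_convention,
    stenosis_reference = cfg$stenosis_reference,
    wall = cfg$wall,
    grid_size = cfg$grid_size,
    materials_source = if (is.list(cfg$materials)) "fitted" else "printed",
    headline_fold_change = headline,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(materials = materials, profiles = profiles,
                 stresses = stresses, foldChanges = ratios, failure = fail,
                 sensitivity = sens, headlineRatio = headline))
}
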