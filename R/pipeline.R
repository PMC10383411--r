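# End-to-end pipeline: simulate (or load) a field survey, map lodging
# severity, map soil fertility, classify the soil line, and emit the
# absorbable-nitrogen risk map and a summary report.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

.readInputs <- function(inputs) {
  need <- c("dtm", "dsm_max", "dsm_harvest", "green", "red", "red_edge",
            "nir", "samples", "boundary")
  missing <- setdiff(need, names(inputs))
  missing <- c(missing, need[vapply(need, function(k)
    !is.null(inputs[[k]]) && !file.exists(inputs[[k]]), TRUE)])
  if (length(missing))
    stop("missing input(s): ", paste(unique(missing), collapse = ", "))
  list(dtm = readAsciiGrid(inputs$dtm),
       dsmMax = readAsciiGrid(inputs$dsm_max),
       dsmHarvest = readAsciiGrid(inputs$dsm_harvest),
       bands = list(green = readAsciiGrid(inputs$green),
                    red = readAsciiGrid(inputs$red),
                    red_edge = readAsciiGrid(inputs$red_edge),
                    nir = readAsciiGrid(inputs$nir)),
       samples = utils::read.csv(inputs$samples),
       boundary = readBoundaryWKT(inputs$boundary))
}

#' Run the full lodging-risk analysis
#'
#' Executes the whole chain: field simulation (or loading of existing
#' rasters/tables), canopy-height and inclination-angle mapping on the
#' analysis mesh, spectral screening and SAN estimation, soil-line
#' classification, and the absorbable-nitrogen risk map. Any stage failure
#' aborts with the stage named. Identical configuration and seed give
#' byte-identical output tables.
#'
#' @param config a \linkS4class{FieldConfig} (also supplies the seed)
#' @param outDir output directory for the mesh CSVs, screening table, model
#'   summary and report; \code{NULL} writes nothing
#' @param inputs optional named list of file paths (dtm, dsm_max,
#'   dsm_harvest, green, red, red_edge, nir, samples, boundary); when given,
#'   simulation is skipped
#' @param meshCellSize analysis-mesh cell size, m (default 1)
#' @param edgeWidth edge-zone width, m (default 4)
#' @param radius buffer radius for the feature table, m (default 0.5)
#' @param onset,guideline risk thresholds, mg N kg^-1
#' @param depth,bulkDensity tillage depth (m) and bulk density (Mg m^-3) for
#'   the fertilizer conversion
#' @param writeRasters also write the theta, delta-CHM and SAN rasters as
#'   ASCII grids (large files; off by default)
#' @return list: field (when simulated), grid, lodgingMesh, screening,
#'   sanModel, fertilityMesh, soilLine, joined, correlation, risk,
#'   report (named numeric summary)
#' @export
fullRun <- function(config = fieldConfig(), outDir = NULL, inputs = NULL,
                    meshCellSize = 1, edgeWidth = 4, radius = 0.5,
                    onset = 140, guideline = 200,
                    depth = 0.1, bulkDensity = 1.0,
                    writeRasters = FALSE) {
  if (is.null(inputs)) {
    field <- .stage("simulate", simulateField(config))
    dtm <- field@dtm; dsmMax <- field@dsmMax; dsmHarvest <- field@dsmHarvest
    bands <- field@bands; samples <- field@samples; boundary <- field@boundary
  } else {
    field <- NULL
    ins <- .stage("load-inputs", .readInputs(inputs))
    dtm <- ins$dtm; dsmMax <- ins$dsmMax; dsmHarvest <- ins$dsmHarvest
    bands <- ins$bands; samples <- ins$samples; boundary <- ins$boundary
  }

  lodgingOut <- .stage("lodging", {
    rChm <- computeCHM(dsmMax, dtm)
    yChm <- computeCHM(dsmHarvest, dtm)
    theta <- inclinationAngle(rChm, yChm)
    delta <- deltaCHM(rChm, yChm)
    grid <- makeMeshGrid(boundary, meshCellSize, edgeWidth)
    list(theta = theta, delta = delta, grid = grid,
         mesh = lodgingMeshMap(theta, delta, grid))
  })

  soilOut <- .stage("soilmap", {
    tab <- buildFeatureTable(bands, samples, radius)
    scr <- screenFeatures(tab, "san")
    best <- scr$feature[which.max(abs(scr$cc))]
    model <- fitSANModel(tab, best)
    sanRaster <- predictSANRaster(model, bands)
    list(table = tab, screening = scr, model = model,
         sanRaster = sanRaster,
         mesh = fertilityMeshMap(sanRaster, lodgingOut$grid))
  })

  lineOut <- .stage("soilline",
                    soilLineAnalysis(bands, seed = config@seed))

  riskOut <- .stage("risk", {
    joined <- suppressMessages(joinMesh(lodgingOut$mesh, soilOut$mesh))
    corr <- correlateInside(joined)
    fert <- fertilizerToSoilN(config@fertilizerN, depth, bulkDensity)
    list(joined = joined, correlation = corr, fert = fert,
         risk = riskMap(joined, fert, onset, guideline))
  })

  report <- c(
    seed = config@seed,
    n_mesh_total = riskOut$correlation$nTotal,
    n_mesh_inside = riskOut$correlation$nInside,
    n_mesh_edge = riskOut$correlation$nEdge,
    inside_fraction = riskOut$correlation$insideFraction,
    san_model_intercept = soilOut$model@intercept,
    san_model_slope = soilOut$model@slope,
    san_model_r_squared = soilOut$model@rSquared,
    pearson_r_inside = riskOut$correlation$pearsonRInside,
    fertilizer_soil_n = riskOut$fert,
    mixel_fraction = lineOut$mixelFraction,
    n_lodging_possible = sum(riskOut$risk$lodging_possible),
    n_above_guideline = sum(riskOut$risk$above_guideline))

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(outDir, f)
    utils::write.csv(lodgingOut$mesh, p("lodging_mesh.csv"),
                     row.names = FALSE)
    utils::write.csv(soilOut$mesh, p("fertility_mesh.csv"),
                     row.names = FALSE)
    utils::write.csv(soilOut$screening, p("screening.csv"),
                     row.names = FALSE)
    utils::write.csv(riskOut$risk, p("risk_mesh.csv"), row.names = FALSE)
    capture <- utils::capture.output(show(soilOut$model),
                                     show(lineOut$model),
                                     show(lineOut$soilLine))
    writeLines(capture, p("models.txt"))
    writeLines(paste(names(report), format(report, digits = 10),
                     sep = " = "), p("report.txt"))
    if (writeRasters) {
      writeAsciiGrid(lodgingOut$theta, p("theta.asc"))
      writeAsciiGrid(lodgingOut$delta, p("delta_chm.asc"))
      writeAsciiGrid(soilOut$sanRaster, p("san.asc"))
    }
  }

  list(field = field, grid = lodgingOut$grid,
       lodgingMesh = lodgingOut$mesh,
       screening = soilOut$screening, sanModel = soilOut$model,
       sanRaster = soilOut$sanRaster,
       fertilityMesh = soilOut$mesh,
       soilLine = lineOut, joined = riskOut$joined,
       correlation = riskOut$correlation, risk = riskOut$risk,
       report = report)
}
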