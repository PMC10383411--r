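#' @import methods
NULL

#' Georeferenced single-band raster
#'
#' A 2-D grid of real values in planar metre coordinates. The origin is the
#' top-left *corner* of the grid; columns run east (increasing x), rows run
#' south (decreasing y). The centre of pixel (i, j) (1-based row i, column j)
#' is at \code{origin + ((j - 0.5) * cellSize, -(i - 0.5) * cellSize)}.
#' Nodata pixels are stored as \code{NA} and propagate through all algebra.
#'
#' Units of the values depend on content: metres for elevation models,
#' reflectance-scaled digital numbers (DN) for spectral bands, mg N kg^-1 for
#' soil-nitrogen maps, degrees for inclination angles.
#'
#' @slot values numeric matrix (rows = north to south, columns = west to east)
#' @slot cellSize metres per pixel (square pixels)
#' @slot origin numeric length-2: planar (x, y) of the top-left corner, metres
#'
#' @aliases FieldRaster
#' @exportClass FieldRaster
setClass("FieldRaster",
  representation(values = "matrix", cellSize = "numeric", origin = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!is.numeric(object@values))
      msg <- c(msg, "'values' must be a numeric matrix")
    if (length(object@cellSize) != 1L || !is.finite(object@cellSize) ||
        object@cellSize <= 0)
      msg <- c(msg, "'cellSize' must be a single positive number")
    if (length(object@origin) != 2L || any(!is.finite(object@origin)))
      msg <- c(msg, "'origin' must be a finite (x, y) pair")
    if (length(msg)) msg else TRUE
  }
)

#' Field boundary polygon
#'
#' A closed polygon in planar metre coordinates (a rectangle in the reference
#' scenario). Vertices are stored without the closing repeat.
#'
#' @slot vertices two-column numeric matrix of (x, y) vertices, metres
#' @exportClass FieldBoundary
setClass("FieldBoundary",
  representation(vertices = "matrix"),
  validity = function(object) {
    v <- object@vertices
    msg <- character()
    if (!is.numeric(v) || ncol(v) != 2L)
      msg <- c(msg, "'vertices' must be a two-column numeric matrix")
    else {
      if (nrow(v) < 3L) msg <- c(msg, "a polygon needs at least 3 vertices")
      else if (abs(.shoelace(v)) <= 0)
        msg <- c(msg, "degenerate boundary: polygon area must be > 0")
      if (anyNA(v)) msg <- c(msg, "vertices must be finite")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Analysis mesh over a field
#'
#' Square cells tiling the boundary's bounding box, anchored at its minimum
#' corner; a cell belongs to the grid iff its centre lies inside the boundary.
#' Cells whose centre lies within \code{edgeWidth} of the boundary polyline are
#' flagged as edge cells (fertilizer-overlap zone); the rest are inside cells.
#'
#' @slot cellSize cell side, metres (1 m in the reference analysis)
#' @slot edgeWidth edge-zone width used for the edge flag, metres
#' @slot cells data.frame with columns \code{mesh_id}, \code{ix}, \code{iy}
#'   (0-based column/row index from the anchor), \code{x}, \code{y} (centre
#'   coordinates) and \code{is_edge}
#' @slot anchor numeric (x, y) of the bounding-box minimum corner
#' @exportClass MeshGrid
setClass("MeshGrid",
  representation(cellSize = "numeric", edgeWidth = "numeric",
                 cells = "data.frame", anchor = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@cellSize <= 0) msg <- c(msg, "'cellSize' must be > 0")
    if (object@edgeWidth < 0) msg <- c(msg, "'edgeWidth' must be >= 0")
    need <- c("mesh_id", "ix", "iy", "x", "y", "is_edge")
    if (!all(need %in% names(object@cells)))
      msg <- c(msg, paste("cells must have columns:", paste(need, collapse = ", ")))
    if (length(msg)) msg else TRUE
  }
)

#' Synthetic field configuration
#'
#' Parameters of the synthetic paddy-field generator. Defaults reproduce the
#' reference scenario: a 55 x 80 m field, band grid at 0.051 m and elevation
#' grid at 0.05 m ground sample distance, SAN varying within 78-200 mg N kg^-1,
#' a 0.15 degree terrain slope, 20 + 15 soil samples and a one-shot basal
#' fertilizer rate of 70 kg N ha^-1.
#'
#' @slot width,height field size, metres
#' @slot bandCellSize,elevationCellSize grid resolutions, metres
#' @slot baseElevation mean terrain elevation, metres
#' @slot slopeDeg terrain slope along the north-south axis, degrees
#' @slot sanRange latent SAN clipping range (min, max), mg N kg^-1
#' @slot sanCorrelationLength spatial correlation length of SAN, metres
#' @slot sanFieldSd amplitude of the correlated SAN variation, mg N kg^-1
#' @slot noiseSdSan soil-sample measurement noise SD, mg N kg^-1
#' @slot noiseSdBand per-pixel band noise SD, DN
#' @slot bandBrightnessSd amplitude of the spatially smooth soil-brightness
#'   variation shared by the bands (it shifts pixels along the soil line and
#'   cancels in band differences), DN
#' @slot noiseSdHeight surface-model noise SD, metres
#' @slot residueFraction proportion of bare-soil pixels that are
#'   vegetation-contaminated mixels
#' @slot nSamplesA,nSamplesB soil-sample counts of the two fields
#' @slot fertilizerN basal fertilizer rate, kg N ha^-1
#' @slot lodgingOnsetSan SAN above which the canopy starts lodging, mg N kg^-1
#' @slot seed integer seed fixing all randomness
#' @exportClass FieldConfig
setClass("FieldConfig",
  representation(
    width = "numeric", height = "numeric",
    bandCellSize = "numeric", elevationCellSize = "numeric",
    baseElevation = "numeric", slopeDeg = "numeric",
    sanRange = "numeric", sanCorrelationLength = "numeric",
    sanFieldSd = "numeric", noiseSdSan = "numeric",
    noiseSdBand = "numeric", bandBrightnessSd = "numeric",
    noiseSdHeight = "numeric",
    residueFraction = "numeric",
    nSamplesA = "numeric", nSamplesB = "numeric",
    fertilizerN = "numeric", lodgingOnsetSan = "numeric",
    seed = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@width <= 0 || object@height <= 0)
      msg <- c(msg, "field dimensions must be positive")
    sr <- object@sanRange
    if (length(sr) != 2L || sr[1] >= sr[2] || sr[1] <= 0 || sr[2] >= 500)
      msg <- c(msg, "'sanRange' must be an increasing pair within (0, 500)")
    if (object@residueFraction < 0 || object@residueFraction > 1)
      msg <- c(msg, "'residueFraction' must be in [0, 1]")
    if (object@nSamplesA < 0 || object@nSamplesB < 0)
      msg <- c(msg, "sample counts must be non-negative")
    if (length(object@seed) != 1L || object@seed != round(object@seed))
      msg <- c(msg, "'seed' must be a single integer")
    if (length(msg)) msg else TRUE
  }
)

#' A complete synthetic field survey
#'
#' Everything the analysis pipeline consumes: bare-soil terrain model, surface
#' models at canopy maximum and at harvest, four reflectance-scaled bands,
#' soil-sample table, field boundary, and the generating truth (latent SAN
#' surface and the coefficients used to render bands and canopy), retained for
#' recovery tests.
#'
#' @slot dtm,dsmMax,dsmHarvest elevation rasters, metres
#' @slot bands named list of FieldRaster: green, red, red_edge, nir (DN)
#' @slot samples data.frame: id, x, y, san, tc, tn
#' @slot boundary FieldBoundary
#' @slot truth list: \code{san} (latent FieldRaster on the band grid),
#'   \code{sanAt} (function (x, y) -> latent SAN), \code{coefficients}
#' @slot config the generating FieldConfig
#' @exportClass SyntheticField
setClass("SyntheticField",
  representation(dtm = "FieldRaster", dsmMax = "FieldRaster",
                 dsmHarvest = "FieldRaster", bands = "list",
                 samples = "data.frame", boundary = "FieldBoundary",
                 truth = "list", config = "FieldConfig"),
  validity = function(object) {
    msg <- character()
    if (!all(c("green", "red", "red_edge", "nir") %in% names(object@bands)))
      msg <- c(msg, "bands must be named green, red, red_edge, nir")
    if (length(msg)) msg else TRUE
  }
)

#' Screened single-regression SAN model
#'
#' Ordinary least-squares fit of soil available nitrogen on one spectral
#' feature (the reference analysis selects green - red), with the Gaussian AIC
#' used to compare candidate features.
#'
#' @slot intercept,slope regression coefficients (SAN = intercept + slope * feature)
#' @slot rSquared coefficient of determination
#' @slot aic Gaussian AIC, n * log(RSS / n) + 2 k with k = 2
#' @slot n number of samples
#' @slot feature feature label, e.g. \code{"diff:green-red"}
#' @exportClass SANLinearModel
setClass("SANLinearModel",
  representation(intercept = "numeric", slope = "numeric",
                 rSquared = "numeric", aic = "numeric", n = "numeric",
                 feature = "character"),
  validity = function(object) {
    msg <- character()
    if (is.finite(object@rSquared) &&
        (object@rSquared < -1e-8 || object@rSquared > 1 + 1e-8))
      msg <- c(msg, "rSquared must lie in [0, 1]")
    if (object@n < 3) msg <- c(msg, "a fit needs n >= 3 samples")
    if (length(msg)) msg else TRUE
  }
)

#' Soil-line logistic classifier
#'
#' Four-band logistic model p = 1 / (1 + exp(-(alpha + sum beta_i X_i)))
#' separating clean soil-line pixels (p >= threshold) from
#' vegetation-contaminated mixels, fitted by iteratively reweighted least
#' squares on standardized predictors and reported on the original DN scale.
#'
#' @slot alpha intercept on the original scale
#' @slot betas named numeric(4): slope per band DN (green, red, red_edge, nir)
#' @slot converged logical
#' @slot nIter IRLS iterations used
#' @slot separated logical: complete separation detected
#' @slot logLik final log-likelihood
#' @slot llTrace per-iteration log-likelihood trace
#' @exportClass SoilLineClassifier
setClass("SoilLineClassifier",
  representation(alpha = "numeric", betas = "numeric", converged = "logical",
                 nIter = "numeric", separated = "logical", logLik = "numeric",
                 llTrace = "numeric"),
  validity = function(object) {
    if (length(object@betas) != 4L)
      "exactly four band coefficients are required" else TRUE
  }
)

#' Red-NIR soil line
#'
#' The linear locus of clean bare-soil pixels in red-NIR DN space:
#' NIR = intercept + slope * red. Pixels well above the line contain
#' vegetation signal.
#'
#' @slot intercept,slope line coefficients, DN
#' @slot rmse root-mean-square residual of the fit, DN
#' @slot n number of pixels used
#' @exportClass SoilLine
setClass("SoilLine",
  representation(intercept = "numeric", slope = "numeric", rmse = "numeric",
                 n = "numeric"),
  validity = function(object) {
    if (object@n < 3) "a soil line needs >= 3 clean pixels" else TRUE
  }
)
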