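# Canopy height model, height collapse, inclination angle and the six-level
# lodging severity map on the analysis mesh.

#' Canopy height model
#'
#' CHM = DSM - DTM on aligned grids. Photogrammetric noise can make the
#' surface model dip below the terrain; negative heights are clamped to 0.
#'
#' @param dsm digital surface model (top of canopy), metres
#' @param dtm digital terrain model (bare ground), metres
#' @return canopy-height FieldRaster, metres
#' @export
computeCHM <- function(dsm, dtm) {
  out <- rasterSubtract(dsm, dtm)
  out@values[!is.na(out@values) & out@values < 0] <- 0
  out
}

#' Canopy height collapse between canopy maximum and harvest
#'
#' delta-CHM = r - y where r is the maximum-season CHM and y the harvest CHM,
#' clamped below at 0.
#'
#' @param rChm maximum CHM raster, metres
#' @param yChm harvest CHM raster, metres
#' @return FieldRaster of height collapse, metres
#' @export
deltaCHM <- function(rChm, yChm) {
  out <- rasterSubtract(rChm, yChm)
  out@values[!is.na(out@values) & out@values < 0] <- 0
  out
}

#' Inclination angle of the canopy at harvest
#'
#' theta = arcsin(y / r) in degrees, assuming plant length at harvest equals
#' the seasonal maximum: 90 degrees is fully upright, 0 flat on the ground.
#' The ratio is clipped to [0, 1] before the arcsine (noise can push y above
#' r), and pixels with maximum CHM below \code{rMin} are set to nodata (no
#' crop; the ratio is unstable on bare patches).
#'
#' @param rChm maximum CHM raster, metres
#' @param yChm harvest CHM raster, metres
#' @param rMin minimum crop height, metres (default 0.05)
#' @return FieldRaster of inclination angle, degrees
#' @export
inclinationAngle <- function(rChm, yChm, rMin = 0.05) {
  .stopifnotAligned(rChm, yChm)
  r <- rChm@values; y <- yChm@values
  ratio <- pmin(pmax(y / r, 0), 1)   # matrix first: pmax keeps its dims
  theta <- asin(ratio) * 180 / pi
  theta[is.na(r) | is.na(y) | r < rMin] <- NA_real_
  fieldRaster(theta, rChm@cellSize, rChm@origin)
}

#' Six-level lodging severity from the inclination angle
#'
#' Quantizes [0, 90] degrees into 18-degree increments: level 0 (no lodging)
#' for theta in (72, 90], ..., level 4 for (0, 18], and level 5 (completely
#' lodged) only at exactly 0 degrees.
#'
#' @param theta inclination angle(s), degrees, in [0, 90]; NA passes through
#' @return integer level(s) 0-5
#' @examples
#' lodgingLevel(c(90, 60, 10, 0))  # 0 1 4 5
#' @export
lodgingLevel <- function(theta) {
  bad <- !is.na(theta) & (theta < 0 | theta > 90)
  if (any(bad))
    stop("inclination angle out of range [0, 90]: ",
         paste(utils::head(theta[bad], 3), collapse = ", "), call. = FALSE)
  out <- ifelse(theta <= 0, 5L, 5L - as.integer(ceiling(theta / 18)))
  as.integer(out)
}

#' Lodging severity map on the analysis mesh
#'
#' Aggregates the inclination-angle and height-collapse rasters to per-cell
#' means, derives the severity level from the cell-mean angle, and carries
#' the edge flag from the grid.
#'
#' @param theta inclination-angle FieldRaster, degrees
#' @param delta delta-CHM FieldRaster, metres
#' @param grid a \linkS4class{MeshGrid}
#' @return data.frame: mesh_id, x, y, delta_chm, theta, level, is_edge,
#'   missing
#' @export
lodgingMeshMap <- function(theta, delta, grid) {
  .stopifnotAligned(theta, delta)
  zt <- zonalMeanMesh(theta, grid)
  zd <- zonalMeanMesh(delta, grid)
  cells <- meshCells(grid)
  data.frame(mesh_id = cells$mesh_id, x = cells$x, y = cells$y,
             delta_chm = zd$mean, theta = zt$mean,
             level = lodgingLevel(zt$mean),
             is_edge = cells$is_edge,
             missing = zt$missing | zd$missing)
}

#' Compare a CHM against ground-surveyed plant heights
#'
#' Buffer-circle CHM means (0.15 m radius by default) at each survey point,
#' paired with the measured height. Photogrammetric CHMs typically
#' underestimate plant height; the mean bias quantifies it.
#'
#' @param chm canopy-height FieldRaster, metres
#' @param survey data.frame with columns x, y, height (metres)
#' @param radius buffer radius, metres
#' @return list: table (per-point chm, height), bias (mean chm - height, m),
#'   correlation (Pearson r; NA with a warning for fewer than 3 points)
#' @export
chmVsMeasured <- function(chm, survey, radius = 0.15) {
  stopifnot(all(c("x", "y", "height") %in% names(survey)))
  est <- vapply(seq_len(nrow(survey)), function(k)
    zonalMeanCircle(chm, c(survey$x[k], survey$y[k]), radius)$mean, 0)
  tab <- data.frame(x = survey$x, y = survey$y,
                    height = survey$height, chm = est,
                    error = est - survey$height)
  r <- if (nrow(tab) >= 3L && stats::sd(tab$height) > 0 &&
           stats::sd(tab$chm) > 0) stats::cor(tab$chm, tab$height)
  else {
    warning("correlation undefined for fewer than 3 varying points")
    NA_real_
  }
  list(table = tab, bias = mean(tab$error), correlation = r)
}
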