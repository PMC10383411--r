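# Spectral feature inventory, single-regression screening against soil
# chemistry, the SAN estimating equation, and the 1 m-mesh fertility map.

.BANDS <- c("green", "red", "red_edge", "nir")
.BAND_PAIRS <- cbind(i = c(1, 1, 1, 2, 2, 3), j = c(2, 3, 4, 3, 4, 4))

#' Normalized difference index
#'
#' NDI(Ri, Rj) = (Ri - Rj) / (Ri + Rj); NDVI is the (NIR, red) special case.
#' Antisymmetric, and bounded in [-1, 1] for non-negative inputs.
#'
#' @param ri,rj band values (DN)
#' @return dimensionless index
#' @export
ndi <- function(ri, rj) {
  s <- ri + rj
  if (any(!is.na(s) & s == 0))
    stop("undefined NDI: ri + rj = 0", call. = FALSE)
  (ri - rj) / s
}

#' NDVI raster
#'
#' Per-pixel NDI(NIR, red); nodata propagates.
#'
#' @param nir,red aligned band FieldRasters
#' @return FieldRaster in [-1, 1]
#' @export
ndviRaster <- function(nir, red) {
  .stopifnotAligned(nir, red)
  s <- nir@values + red@values
  v <- (nir@values - red@values) / s
  v[!is.na(s) & s == 0] <- NA_real_
  fieldRaster(v, nir@cellSize, nir@origin)
}

#' The 28-feature spectral inventory
#'
#' Enumerates 4 single bands, 6 pairwise differences, 6 sums, 6 ratios and 6
#' NDIs over (green, red, Red edge, NIR), in that fixed order. This order
#' breaks ties in screening.
#'
#' @return data.frame: feature (label), family, band_i, band_j (NA for
#'   single-band features)
#' @export
featureInventory <- function() {
  singles <- data.frame(family = "single", band_i = .BANDS,
                        band_j = NA_character_)
  two <- function(fam) data.frame(family = fam,
                                  band_i = .BANDS[.BAND_PAIRS[, "i"]],
                                  band_j = .BANDS[.BAND_PAIRS[, "j"]])
  inv <- rbind(singles, two("difference"), two("sum"), two("ratio"),
               two("ndi"))
  sep <- c(single = "", difference = "-", sum = "+", ratio = "/", ndi = ",")
  inv$feature <- ifelse(is.na(inv$band_j), inv$band_i,
                        paste0(inv$family, ":", inv$band_i,
                               sep[inv$family], inv$band_j))
  inv[, c("feature", "family", "band_i", "band_j")]
}

# evaluate one inventory feature from named band values (vectors ok)
.evalFeature <- function(spec, bandValues) {
  bi <- bandValues[[spec$band_i]]
  if (spec$family == "single") return(bi)
  bj <- bandValues[[spec$band_j]]
  switch(spec$family,
         difference = bi - bj,
         sum = bi + bj,
         ratio = bi / bj,
         ndi = ndi(bi, bj),
         stop("unknown feature family: ", spec$family))
}

#' Buffer-mean band values and spectral features at soil sampling points
#'
#' For each sample, averages every band over a buffer circle at the sampling
#' point (0.5 m radius by default), then computes all 28 inventory features
#' from the four band means.
#'
#' @param bands named list of FieldRasters: green, red, red_edge, nir
#' @param samples data.frame with columns id, x, y and the soil chemistry
#'   (san, tc, tn, ...)
#' @param radius buffer radius, metres (reference radii: 0.15, 0.25, 0.5)
#' @return the samples table with one added column per band mean and per
#'   feature
#' @export
buildFeatureTable <- function(bands, samples, radius = 0.5) {
  stopifnot(all(.BANDS %in% names(bands)))
  means <- lapply(.BANDS, function(b) {
    vapply(seq_len(nrow(samples)), function(k) {
      tryCatch(
        zonalMeanCircle(bands[[b]], c(samples$x[k], samples$y[k]),
                        radius)$mean,
        error = function(e) stop("empty buffer for sample id ",
                                 samples$id[k], " on band ", b,
                                 call. = FALSE))
    }, 0)
  })
  names(means) <- .BANDS
  out <- samples
  for (b in .BANDS) out[[paste0("mean_", b)]] <- means[[b]]
  inv <- featureInventory()
  for (k in seq_len(nrow(inv)))
    out[[inv$feature[k]]] <- .evalFeature(inv[k, ], means)
  out
}

#' Screen single regressions of soil chemistry on each spectral feature
#'
#' Pearson correlation of every inventory feature with the explained soil
#' variable, sorted by absolute correlation (descending); ties are broken by
#' inventory order. A zero-variance feature is kept with a missing
#' correlation rather than silently dropped.
#'
#' @param table output of \code{\link{buildFeatureTable}}
#' @param explained column name of the explained variable: "san", "tc" or
#'   "tn"
#' @return data.frame: feature, family, cc, rank
#' @export
screenFeatures <- function(table, explained = "san") {
  stopifnot(explained %in% names(table))
  yv <- table[[explained]]
  if (nrow(table) < 3L) stop("need >= 3 samples", call. = FALSE)
  if (stats::sd(yv) == 0)
    stop("explained variable is constant", call. = FALSE)
  inv <- featureInventory()
  cc <- vapply(inv$feature, function(f) {
    x <- table[[f]]
    if (is.null(x)) stop("feature column missing: ", f, call. = FALSE)
    if (stats::sd(x) == 0) NA_real_ else stats::cor(x, yv)
  }, 0)
  out <- data.frame(feature = inv$feature, family = inv$family, cc = cc,
                    row.names = NULL)
  ord <- order(-abs(out$cc), seq_len(nrow(out)), na.last = TRUE)
  out <- out[ord, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Fit the SAN estimating equation
#'
#' Ordinary least squares of the explained soil variable on one spectral
#' feature (SAN on green - red in the reference analysis, giving
#' SAN = 287.86 - 0.046 (green - red)). The Gaussian AIC
#' n log(RSS / n) + 2k with k = 2 is reported for comparing features.
#'
#' @param table output of \code{\link{buildFeatureTable}}
#' @param feature feature label from \code{\link{featureInventory}}
#' @param explained explained-variable column (default "san")
#' @return a \linkS4class{SANLinearModel}
#' @export
fitSANModel <- function(table, feature = "difference:green-red",
                        explained = "san") {
  x <- table[[feature]]
  yv <- table[[explained]]
  if (is.null(x)) stop("feature column missing: ", feature, call. = FALSE)
  n <- length(yv)
  if (n < 3L) stop("need >= 3 samples", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("singular fit: feature has zero variance", call. = FALSE)
  fit <- stats::lm(yv ~ x)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((yv - mean(yv))^2)
  new("SANLinearModel",
      intercept = unname(stats::coef(fit)[1]),
      slope = unname(stats::coef(fit)[2]),
      rSquared = if (tss > 0) 1 - rss / tss else NA_real_,
      aic = n * log(rss / n) + 2 * 2,
      n = n, feature = feature)
}

#' Predict a SAN raster from the fitted model
#'
#' Evaluates the estimating equation per pixel on the band rasters; nodata
#' propagates. Optionally clips to a plausibility range (off by default).
#'
#' @param model a \linkS4class{SANLinearModel}
#' @param bands named list of band FieldRasters
#' @param clipRange optional (min, max) clipping, mg N kg^-1
#' @return SAN FieldRaster, mg N kg^-1
#' @export
predictSANRaster <- function(model, bands, clipRange = NULL) {
  inv <- featureInventory()
  spec <- inv[inv$feature == model@feature, ]
  if (nrow(spec) != 1L)
    stop("unknown feature: ", model@feature, call. = FALSE)
  need <- stats::na.omit(c(spec$band_i, spec$band_j))
  if (!all(need %in% names(bands)))
    stop("missing band(s): ",
         paste(setdiff(need, names(bands)), collapse = ", "), call. = FALSE)
  ref <- bands[[spec$band_i]]
  vals <- .evalFeature(spec, lapply(bands, function(b) b@values))
  san <- model@intercept + model@slope * vals
  if (!is.null(clipRange))
    san <- pmin(clipRange[2], pmax(clipRange[1], san))
  fieldRaster(matrix(san, nrow(ref@values), ncol(ref@values)),
              ref@cellSize, ref@origin)
}

#' Soil fertility map on the analysis mesh
#'
#' Per-cell mean estimated SAN, with a flag for the agronomic optimum range
#' (80-200 mg N kg^-1 by default).
#'
#' @param san SAN FieldRaster, mg N kg^-1
#' @param grid a \linkS4class{MeshGrid}
#' @param optimum (min, max) optimum SAN range, mg N kg^-1
#' @return data.frame: mesh_id, x, y, san_est, n, missing, in_optimum,
#'   is_edge
#' @export
fertilityMeshMap <- function(san, grid, optimum = c(80, 200)) {
  z <- zonalMeanMesh(san, grid)
  cells <- meshCells(grid)
  data.frame(mesh_id = cells$mesh_id, x = cells$x, y = cells$y,
             san_est = z$mean, n = z$n, missing = z$missing,
             in_optimum = !is.na(z$mean) & z$mean >= optimum[1] &
               z$mean <= optimum[2],
             is_edge = cells$is_edge)
}
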