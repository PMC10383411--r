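# Synthetic paddy-field generator: a latent soil-available-nitrogen (SAN)
# surface drives both the bare-soil spectral bands and the canopy collapse,
# reproducing the statistical structure the downstream analysis assumes.

# Band-rendering coefficients: the SAN <-> (green - red) link is the inverse
# of the estimating equation SAN = 287.86 - 0.046 (green - red), so that the
# printed coefficients are recoverable from noise-free synthetic samples.
.SAN_INTERCEPT <- 287.86
.SAN_SLOPE <- -0.046
.SOIL_LINE_INTERCEPT <- 2000
.SOIL_LINE_SLOPE <- 1.2
.MIXEL_NIR_OFFSET <- 2500
.MIXEL_NIR_SD <- 800
.RED_BASE <- 8500
.RED_PER_SAN <- -8
.EDGE_LODGE_WIDTH <- 4      # m: strip that lodges regardless of SAN
.EDGE_LODGE_THETA <- 15     # degrees
.THETA_FLOOR <- 10          # degrees at the top of the SAN range

# run expr with a fixed seed without disturbing the caller's RNG stream
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Synthetic field configuration
#'
#' Constructor with the reference-scenario defaults; see
#' \linkS4class{FieldConfig} for the meaning and units of each parameter.
#'
#' @param width,height field size, metres
#' @param bandCellSize,elevationCellSize grid resolutions, metres
#' @param baseElevation mean terrain elevation, metres
#' @param slopeDeg terrain slope, degrees
#' @param sanRange SAN clipping range, mg N kg^-1
#' @param sanCorrelationLength SAN spatial correlation length, metres
#' @param sanFieldSd amplitude of correlated SAN variation, mg N kg^-1
#' @param noiseSdSan soil-sample measurement noise SD, mg N kg^-1
#' @param noiseSdBand per-pixel band noise SD, DN
#' @param bandBrightnessSd smooth soil-brightness variation SD, DN
#' @param noiseSdHeight surface-model noise SD, metres
#' @param residueFraction mixel (crop-residue) pixel fraction
#' @param nSamplesA,nSamplesB soil-sample counts
#' @param fertilizerN basal fertilizer rate, kg N ha^-1
#' @param lodgingOnsetSan lodging-onset SAN, mg N kg^-1
#' @param seed integer seed
#' @return a \linkS4class{FieldConfig}
#' @export
fieldConfig <- function(width = 55, height = 80,
                        bandCellSize = 0.051, elevationCellSize = 0.05,
                        baseElevation = 4.7, slopeDeg = 0.15,
                        sanRange = c(78, 200), sanCorrelationLength = 10,
                        sanFieldSd = 20, noiseSdSan = 8,
                        noiseSdBand = 50, bandBrightnessSd = 2000,
                        noiseSdHeight = 0.03,
                        residueFraction = 0.1,
                        nSamplesA = 20, nSamplesB = 15,
                        fertilizerN = 70, lodgingOnsetSan = 140,
                        seed = 1) {
  new("FieldConfig", width = width, height = height,
      bandCellSize = bandCellSize, elevationCellSize = elevationCellSize,
      baseElevation = baseElevation, slopeDeg = slopeDeg,
      sanRange = sanRange, sanCorrelationLength = sanCorrelationLength,
      sanFieldSd = sanFieldSd, noiseSdSan = noiseSdSan,
      noiseSdBand = noiseSdBand, bandBrightnessSd = bandBrightnessSd,
      noiseSdHeight = noiseSdHeight,
      residueFraction = residueFraction,
      nSamplesA = nSamplesA, nSamplesB = nSamplesB,
      fertilizerN = fertilizerN, lodgingOnsetSan = lodgingOnsetSan,
      seed = seed)
}

# Latent SAN surface: a deterministic north-high / centre-high trend plus a
# spatially correlated component, as one well-defined function of (x, y), so
# the band grid, the elevation grid and the point samples all see the same
# truth. The correlated component is bilinear interpolation of a white-noise
# lattice with spacing = the correlation length; when the correlation length
# does not exceed the band cell size, it degrades to i.i.d. pixel noise
# (nearest-node lookup on a lattice at the cell size).
# spatially correlated zero-mean noise surface as a function of (x, y)
.latticeField <- function(cfg, seed, sd) {
  W <- cfg@width; H <- cfg@height
  L <- cfg@sanCorrelationLength
  nearest <- L <= cfg@bandCellSize
  spacing <- max(L, cfg@bandCellSize)
  nx <- ceiling(W / spacing) + 3L
  ny <- ceiling(H / spacing) + 3L
  z <- .withSeed(seed, matrix(stats::rnorm(nx * ny, sd = sd), ny, nx))
  function(x, y) {
    u <- x / spacing + 1          # lattice coordinates, node 1 at -spacing
    v <- y / spacing + 1
    if (nearest) {
      z[cbind(pmin(ny, pmax(1L, floor(v) + 1L)),
              pmin(nx, pmax(1L, floor(u) + 1L)))]
    } else {
      i0 <- pmin(nx - 1L, pmax(1L, floor(u))); fu <- u - i0
      j0 <- pmin(ny - 1L, pmax(1L, floor(v))); fv <- v - j0
      z[cbind(j0, i0)] * (1 - fu) * (1 - fv) +
        z[cbind(j0, i0 + 1L)] * fu * (1 - fv) +
        z[cbind(j0 + 1L, i0)] * (1 - fu) * fv +
        z[cbind(j0 + 1L, i0 + 1L)] * fu * fv
    }
  }
}

.sanLatent <- function(cfg) {
  smin <- cfg@sanRange[1]; smax <- cfg@sanRange[2]
  span <- smax - smin
  W <- cfg@width; H <- cfg@height
  noise <- .latticeField(cfg, cfg@seed + 101, cfg@sanFieldSd)
  trend <- function(x, y)
    smin + 0.25 * span + 0.50 * span * (y / H) +
      0.12 * span * exp(-(x - W / 2)^2 / (2 * (W / 4)^2))
  function(x, y)
    pmin(smax, pmax(smin, trend(x, y) + noise(x, y)))
}

# evaluate f(x, y) on the pixel centres of a width x height grid
.evalOnGrid <- function(cfg, cellSize, f) {
  ncols <- as.integer(ceiling(cfg@width / cellSize - 1e-9))
  nrows <- as.integer(ceiling(cfg@height / cellSize - 1e-9))
  xs <- (seq_len(ncols) - 0.5) * cellSize
  ys <- cfg@height - (seq_len(nrows) - 0.5) * cellSize   # row 1 = north
  m <- matrix(f(rep(xs, each = nrows), rep(ys, times = ncols)), nrows, ncols)
  fieldRaster(m, cellSize, origin = c(0, cfg@height))
}

#' Latent SAN surface of a synthetic field
#'
#' Smooth, spatially correlated soil-available-nitrogen field, higher on the
#' north and centre and lower towards the south, clipped to
#' \code{sanRange} (78-200 mg N kg^-1 by default). Deterministic given the
#' configuration seed.
#'
#' @param cfg a \linkS4class{FieldConfig}
#' @param cellSize grid resolution, metres (default the band grid)
#' @return a \linkS4class{FieldRaster} of SAN, mg N kg^-1
#' @export
generateSANField <- function(cfg, cellSize = cfg@bandCellSize) {
  .evalOnGrid(cfg, cellSize, .sanLatent(cfg))
}

#' Render the four bare-soil spectral bands from a SAN surface
#'
#' The green - red difference is linked to SAN by inverting the estimating
#' equation (green - red = (287.86 - SAN) / 0.046) plus Gaussian noise. Red
#' carries, besides a weak SAN coupling, a spatially smooth soil-brightness
#' component (moisture/texture variation) that is shared with green — so it
#' cancels exactly in the difference — and shifts clean NIR *along* the
#' red-NIR soil line; band ratios and NDIs are therefore noisier proxies for
#' SAN than the difference, as observed on real bare-soil scenes. A
#' \code{residueFraction} subpopulation of mixels gets elevated NIR (and a
#' partial Red-edge lift); Red edge otherwise co-varies with green, so their
#' difference carries no SAN signal, as on real bare soil.
#'
#' @param san SAN FieldRaster on the target band grid, mg N kg^-1
#' @param cfg a \linkS4class{FieldConfig}
#' @return list: bands (green, red, red_edge, nir FieldRasters),
#'   mixelMask (logical matrix), coefficients (generating constants)
#' @export
renderBands <- function(san, cfg) {
  stopifnot(is(san, "FieldRaster"))
  s <- san@values
  d <- dim(s)
  npx <- length(s)
  pc <- pixelCentres(san)
  px <- rep(pc$x, each = d[1]); py <- rep(pc$y, times = d[2])
  bright <- .latticeField(cfg, cfg@seed + 203, cfg@bandBrightnessSd)(px, py)
  # idiosyncratic smooth variation of the longer-wavelength bands: dilutes
  # any SAN signal reaching red edge / NIR combinations, as in real scenes
  idioRe <- .latticeField(cfg, cfg@seed + 204,
                          0.8 * cfg@bandBrightnessSd)(px, py)
  idioNir <- .latticeField(cfg, cfg@seed + 205,
                           0.25 * cfg@bandBrightnessSd)(px, py)
  .withSeed(cfg@seed + 202, {
    red <- .RED_BASE + .RED_PER_SAN * (s - mean(cfg@sanRange)) +
      matrix(bright, d[1], d[2]) +
      stats::rnorm(npx, sd = cfg@noiseSdBand)
    green <- red + (.SAN_INTERCEPT - s) / (-.SAN_SLOPE) +
      stats::rnorm(npx, sd = cfg@noiseSdBand)
    mixel <- matrix(stats::runif(npx) < cfg@residueFraction, d[1], d[2])
    lift <- matrix(0, d[1], d[2])
    if (any(mixel))
      lift[mixel] <- .MIXEL_NIR_OFFSET +
        abs(stats::rnorm(sum(mixel), sd = .MIXEL_NIR_SD))
    nir <- .SOIL_LINE_INTERCEPT + .SOIL_LINE_SLOPE * red + lift +
      matrix(idioNir, d[1], d[2]) + stats::rnorm(npx, sd = cfg@noiseSdBand)
    # red edge co-varies with green (their difference carries no SAN
    # signal, as on real bare soil) and sees half of the vegetation lift
    redEdge <- green - 1200 + 0.5 * lift + matrix(idioRe, d[1], d[2]) +
      stats::rnorm(npx, sd = cfg@noiseSdBand)
    mk <- function(v) fieldRaster(matrix(v, d[1], d[2]), san@cellSize,
                                  san@origin)
    list(bands = list(green = mk(green), red = mk(red),
                      red_edge = mk(redEdge), nir = mk(nir)),
         mixelMask = mixel,
         coefficients = c(sanIntercept = .SAN_INTERCEPT,
                          sanSlope = .SAN_SLOPE,
                          soilLineIntercept = .SOIL_LINE_INTERCEPT,
                          soilLineSlope = .SOIL_LINE_SLOPE))
  })
}

# lodging response: upright (90 deg) below the onset SAN, linear decrease to
# the theta floor at the top of the SAN range; an edge strip lodges
# regardless of SAN (fertilizer-overlap artefact).
.lodgingTheta <- function(san, cfg, distEdge) {
  smax <- cfg@sanRange[2]
  onset <- cfg@lodgingOnsetSan
  theta <- ifelse(san <= onset, 90,
                  pmax(.THETA_FLOOR,
                       90 - (90 - .THETA_FLOOR) * (san - onset) / (smax - onset)))
  ifelse(distEdge < .EDGE_LODGE_WIDTH, pmin(theta, .EDGE_LODGE_THETA), theta)
}

#' Render terrain and canopy surface models from a SAN surface
#'
#' The bare-soil terrain is a gently sloping plane (0.15 degrees by default,
#' north end higher). Maximum canopy height r grows from 0.5 to 0.7 m across
#' the SAN range; the harvest surface collapses where SAN exceeds the lodging
#' onset (inclination angle falling linearly from 90 to 10 degrees at the top
#' of the range), and a 4 m edge strip lodges regardless of SAN.
#'
#' @param san SAN FieldRaster on the target elevation grid
#' @param cfg a \linkS4class{FieldConfig}
#' @return list of FieldRasters: dtm, dsmMax, dsmHarvest (metres)
#' @export
renderCanopy <- function(san, cfg) {
  stopifnot(is(san, "FieldRaster"))
  s <- san@values
  d <- dim(s)
  pc <- pixelCentres(san)
  px <- matrix(rep(pc$x, each = d[1]), d[1], d[2])
  py <- matrix(rep(pc$y, times = d[2]), d[1], d[2])
  smin <- cfg@sanRange[1]; smax <- cfg@sanRange[2]
  dtmV <- cfg@baseElevation +
    tan(cfg@slopeDeg * pi / 180) * (py - cfg@height / 2)
  r <- 0.5 + 0.2 * (s - smin) / (smax - smin)
  distEdge <- pmin(px, cfg@width - px, py, cfg@height - py)
  theta <- .lodgingTheta(s, cfg, distEdge)
  y <- r * sin(theta * pi / 180)
  .withSeed(cfg@seed + 303, {
    dsmMaxV <- dtmV + r + stats::rnorm(length(s), sd = cfg@noiseSdHeight)
    dsmHarvV <- dtmV + y + stats::rnorm(length(s), sd = cfg@noiseSdHeight)
    list(dtm = fieldRaster(dtmV, san@cellSize, san@origin),
         dsmMax = fieldRaster(matrix(dsmMaxV, d[1], d[2]), san@cellSize,
                              san@origin),
         dsmHarvest = fieldRaster(matrix(dsmHarvV, d[1], d[2]), san@cellSize,
                                  san@origin))
  })
}

#' Draw soil samples from the latent SAN surface
#'
#' Places \code{nSamplesA + nSamplesB} points on a jittered grid inside the
#' field and measures SAN with Gaussian noise; total carbon and nitrogen are
#' generated with a weak positive link to SAN.
#'
#' @param cfg a \linkS4class{FieldConfig}
#' @param sanAt latent surface function (x, y) -> SAN; defaults to the
#'   surface defined by \code{cfg}
#' @return data.frame: id, x, y, san (mg N kg^-1), tc (\%), tn (\%)
#' @export
samplePoints <- function(cfg, sanAt = .sanLatent(cfg)) {
  n <- cfg@nSamplesA + cfg@nSamplesB
  if (n < 1) stop("at least one sample is required", call. = FALSE)
  if (n > floor(cfg@width) * floor(cfg@height))
    stop("more samples than 1 m cells in the field", call. = FALSE)
  nxs <- ceiling(sqrt(n * cfg@width / cfg@height))
  nys <- ceiling(n / nxs)
  cw <- cfg@width / nxs; ch <- cfg@height / nys
  ij <- expand.grid(i = seq_len(nxs), j = seq_len(nys))[seq_len(n), ]
  .withSeed(cfg@seed + 404, {
    jx <- stats::runif(n, -0.3, 0.3) * cw
    jy <- stats::runif(n, -0.3, 0.3) * ch
    x <- pmin(cfg@width - 0.5, pmax(0.5, (ij$i - 0.5) * cw + jx))
    y <- pmin(cfg@height - 0.5, pmax(0.5, (ij$j - 0.5) * ch + jy))
    latent <- sanAt(x, y)
    san <- latent + stats::rnorm(n, sd = cfg@noiseSdSan)
    tc <- 2.0 + 0.0015 * (san - mean(cfg@sanRange)) +
      stats::rnorm(n, sd = 0.15)
    tn <- tc / 11.5 + stats::rnorm(n, sd = 0.012)
    data.frame(id = seq_len(n), x = x, y = y, san = san,
               tc = tc, tn = tn)
  })
}

#' Simulate a complete synthetic field survey
#'
#' Runs the latent-SAN, band, canopy and sampling generators with seeds
#' derived from \code{cfg@seed}; all outputs are reproducible bit-for-bit
#' under the same configuration.
#'
#' @param cfg a \linkS4class{FieldConfig}
#' @return a \linkS4class{SyntheticField}
#' @examples
#' fld <- simulateField(fieldConfig(width = 12, height = 16,
#'                                  bandCellSize = 0.4,
#'                                  elevationCellSize = 0.4, seed = 7))
#' fld
#' @export
simulateField <- function(cfg) {
  sanAt <- .sanLatent(cfg)
  sanBand <- .evalOnGrid(cfg, cfg@bandCellSize, sanAt)
  sanElev <- .evalOnGrid(cfg, cfg@elevationCellSize, sanAt)
  bb <- renderBands(sanBand, cfg)
  cc <- renderCanopy(sanElev, cfg)
  samples <- samplePoints(cfg, sanAt)
  new("SyntheticField",
      dtm = cc$dtm, dsmMax = cc$dsmMax, dsmHarvest = cc$dsmHarvest,
      bands = bb$bands, samples = samples,
      boundary = rectangularBoundary(cfg@width, cfg@height),
      truth = list(san = sanBand, sanAt = sanAt,
                   coefficients = bb$coefficients,
                   mixelMask = bb$mixelMask),
      config = cfg)
}

#' Write a synthetic field survey to disk
#'
#' Writes the elevation models and bands as ESRI ASCII grids, the samples as
#' CSV and the boundary as WKT, in the formats the analysis functions read
#' back.
#'
#' @param field a \linkS4class{SyntheticField}
#' @param dir output directory (created if absent)
#' @return named character vector of the files written
#' @export
writeSyntheticField <- function(field, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  writeAsciiGrid(field@dtm, p("dtm.asc"))
  writeAsciiGrid(field@dsmMax, p("dsm_max.asc"))
  writeAsciiGrid(field@dsmHarvest, p("dsm_harvest.asc"))
  for (b in names(field@bands))
    writeAsciiGrid(field@bands[[b]], p(paste0("band_", b, ".asc")))
  utils::write.csv(field@samples, p("samples.csv"), row.names = FALSE)
  writeBoundaryWKT(field@boundary, p("boundary.wkt"))
  c(dtm = p("dtm.asc"), dsm_max = p("dsm_max.asc"),
    dsm_harvest = p("dsm_harvest.asc"),
    vapply(names(field@bands),
           function(b) p(paste0("band_", b, ".asc")), ""),
    samples = p("samples.csv"), boundary = p("boundary.wkt"))
}
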