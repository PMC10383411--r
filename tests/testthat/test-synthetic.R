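test_that("field simulation is deterministic and respects the SAN range", {
  cfg <- smallConfig(seed = 5)
  f1 <- simulateField(cfg)
  f2 <- simulateField(cfg)
  expect_identical(rasterValues(f1@truth$san), rasterValues(f2@truth$san))
  expect_identical(rasterValues(f1@dsmHarvest), rasterValues(f2@dsmHarvest))
  expect_identical(rasterValues(f1@bands$nir), rasterValues(f2@bands$nir))
  expect_identical(f1@samples, f2@samples)

  for (sd in c(1, 99, 20250)) {
    san <- generateSANField(smallConfig(seed = sd))
    v <- rasterValues(san)
    expect_true(all(v >= 78 & v <= 200))
  }
  # the latent surface trends north (high) to south (low)
  v <- rasterValues(generateSANField(smallConfig(seed = 5)))
  north <- mean(v[seq_len(nrow(v) %/% 3), ])
  south <- mean(v[(2 * nrow(v) %/% 3):nrow(v), ])
  expect_gt(north, south)
})

test_that("correlation length controls spatial autocorrelation of SAN", {
  lag1 <- function(cfg) {
    noisy <- rasterValues(generateSANField(cfg))
    flat <- rasterValues(generateSANField(
      fieldConfig(width = cfg@width, height = cfg@height,
                  bandCellSize = cfg@bandCellSize,
                  elevationCellSize = cfg@elevationCellSize,
                  sanRange = cfg@sanRange, sanFieldSd = 0,
                  sanCorrelationLength = cfg@sanCorrelationLength,
                  seed = cfg@seed)))
    n <- noisy - flat        # isolates the stochastic component
    cor(as.vector(n[, -1]), as.vector(n[, -ncol(n)]))
  }
  wide <- c(10, 490)         # keep clipping from binding
  iid <- lag1(fieldConfig(width = 12, height = 12, bandCellSize = 0.2,
                          elevationCellSize = 0.2, sanRange = wide,
                          sanCorrelationLength = 0.001, seed = 8))
  smooth <- lag1(fieldConfig(width = 12, height = 12, bandCellSize = 0.2,
                             elevationCellSize = 0.2, sanRange = wide,
                             sanCorrelationLength = 5, seed = 8))
  expect_lt(abs(iid), 0.1)
  expect_gt(smooth, 0.8)
})

test_that("noise-free bands invert the SAN estimating relation exactly", {
  cfg <- smallConfig(noiseSdBand = 0, bandBrightnessSd = 0,
                     residueFraction = 0)
  san <- fieldRaster(matrix(c(200, 78, 139, 156), 2, 2), 1, c(0, 2))
  bb <- renderBands(san, cfg)
  gr <- rasterValues(bb$bands$green) - rasterValues(bb$bands$red)
  expect_equal(gr[1, 1], (287.86 - 200) / 0.046, tolerance = 1e-12)  # 1910
  expect_equal(gr[2, 1], (287.86 - 78) / 0.046, tolerance = 1e-12)   # 4562.17
  expect_equal(gr[1, 1], 1910, tolerance = 1e-9)

  # clean pixels sit exactly on the soil line when residueFraction = 0
  red <- rasterValues(bb$bands$red); nir <- rasterValues(bb$bands$nir)
  co <- bb$coefficients
  expect_equal(nir, co["soilLineIntercept"] + co["soilLineSlope"] * red,
               tolerance = 1e-9, ignore_attr = TRUE)

  # with residue, the flagged mixels lie above the line
  cfgMix <- smallConfig(noiseSdBand = 0, bandBrightnessSd = 0,
                        residueFraction = 0.5)
  bm <- renderBands(generateSANField(cfgMix), cfgMix)
  resid <- rasterValues(bm$bands$nir) -
    (co["soilLineIntercept"] + co["soilLineSlope"] *
       rasterValues(bm$bands$red))
  expect_true(all(resid[bm$mixelMask] > 0))
  expect_true(all(abs(resid[!bm$mixelMask]) < 1e-9))
})

test_that("canopy collapse follows the lodging response", {
  cfg <- smallConfig(noiseSdHeight = 0)
  san <- generateSANField(cfg, cellSize = cfg@elevationCellSize)
  cc <- renderCanopy(san, cfg)
  r <- rasterValues(cc$dsmMax) - rasterValues(cc$dtm)
  y <- rasterValues(cc$dsmHarvest) - rasterValues(cc$dtm)
  pc <- pixelCentres(san)
  interior <- outer(pmin(pc$y, cfg@height - pc$y) > 4,
                    pmin(pc$x, cfg@width - pc$x) > 4, "&")
  sanV <- rasterValues(san)

  below <- interior & sanV <= 140
  expect_true(any(below))
  expect_equal(y[below], r[below], tolerance = 1e-12)   # upright: theta 90

  top <- interior & sanV >= 199.9
  if (any(top)) expect_true(all(y[top] / r[top] < sin(18 * pi / 180)))

  expect_true(all(r >= 0.5 - 1e-9 & r <= 0.7 + 1e-9))

  # the edge strip lodges regardless of SAN
  edge <- !interior & sanV <= 140
  expect_true(all(y[edge] / r[edge] <= sin(15 * pi / 180) + 1e-9))

  cc2 <- renderCanopy(san, cfg)
  expect_identical(rasterValues(cc$dsmHarvest), rasterValues(cc2$dsmHarvest))
})

test_that("soil sampling emits the configured count and hits the latent truth", {
  s <- samplePoints(fieldConfig())
  expect_equal(nrow(s), 35L)   # 20 + 15 samples

  cfg <- smallConfig(noiseSdSan = 0)
  s0 <- samplePoints(cfg)
  latent <- simulateField(cfg)@truth$sanAt
  expect_equal(s0$san, latent(s0$x, s0$y), tolerance = 1e-12)
  expect_identical(s0, samplePoints(cfg))
  expect_true(all(s0$x > 0 & s0$x < cfg@width &
                  s0$y > 0 & s0$y < cfg@height))

  expect_error(samplePoints(fieldConfig(width = 3, height = 3)),
               "more samples")
})

test_that("generated terrain slope is recovered by a plane fit", {
  cfg <- smallConfig()
  fld <- simulateField(cfg)
  v <- rasterValues(fld@dtm)
  pc <- pixelCentres(fld@dtm)
  d <- dim(v)
  df <- data.frame(z = as.vector(v),
                   x = rep(pc$x, each = d[1]),
                   y = rep(pc$y, times = d[2]))
  co <- coef(lm(z ~ x + y, data = df))
  slope <- atan(sqrt(co["x"]^2 + co["y"]^2)) * 180 / pi
  expect_equal(unname(slope), 0.15, tolerance = 0.01 / 0.15)
})
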