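test_that("normalized difference index obeys its algebra", {
  expect_equal(ndi(1000, 1000), 0)
  expect_equal(ndi(3, 1), 0.5)
  expect_error(ndi(5, -5), "undefined")
  set.seed(3)
  a <- runif(50, 1, 1e4); b <- runif(50, 1, 1e4)
  expect_equal(ndi(a, b), -ndi(b, a))
  expect_true(all(ndi(a, b) >= -1 & ndi(a, b) <= 1))

  nir <- fieldRaster(matrix(c(300, 300, NA), 1, 3), 1, c(0, 1))
  red <- fieldRaster(matrix(c(300, 100, 100), 1, 3), 1, c(0, 1))
  nv <- rasterValues(ndviRaster(nir, red))
  expect_equal(nv[1, 1], 0)
  expect_equal(nv[1, 2], 0.5)
  expect_true(is.na(nv[1, 3]))
})

test_that("the feature inventory enumerates 4 + 6 + 6 + 6 + 6 features", {
  inv <- featureInventory()
  expect_equal(nrow(inv), 28L)
  expect_equal(as.integer(table(inv$family)[c("single", "difference", "sum",
                                              "ratio", "ndi")]),
               c(4L, 6L, 6L, 6L, 6L))
  expect_false(anyDuplicated(inv$feature) > 0)
  two <- inv[inv$family != "single", ]
  expect_true(all(two$band_i != two$band_j))
})

test_that("feature table uses buffer means and degenerates correctly", {
  const <- function(v) fieldRaster(matrix(v, 20, 20), 0.5, c(0, 10))
  bands <- list(green = const(1000), red = const(1000),
                red_edge = const(1000), nir = const(1000))
  samples <- data.frame(id = 1:3, x = c(2, 5, 8), y = c(2, 5, 8),
                        san = c(100, 150, 120))
  tab <- buildFeatureTable(bands, samples, radius = 0.5)
  inv <- featureInventory()
  expect_true(all(inv$feature %in% names(tab)))
  for (f in inv$feature[inv$family == "difference"])
    expect_true(all(tab[[f]] == 0))
  for (f in inv$feature[inv$family == "ratio"])
    expect_true(all(tab[[f]] == 1))
  for (f in inv$feature[inv$family == "ndi"])
    expect_true(all(tab[[f]] == 0))

  # buffer means agree with the exhaustive circle oracle
  set.seed(21)
  bands$red <- fieldRaster(matrix(runif(400, 5e3, 9e3), 20, 20), 0.5,
                           c(0, 10))
  tab <- buildFeatureTable(bands, samples, radius = 0.5)
  for (k in 1:3)
    expect_equal(tab$mean_red[k],
                 unname(oracleCircleMean(bands$red,
                                         c(samples$x[k], samples$y[k]),
                                         0.5)["mean"]),
                 tolerance = 1e-12)

  out <- samples; out$x[2] <- 50
  expect_error(buildFeatureTable(bands, out, 0.5), "sample id 2")
})

test_that("screening ranks by |cc|, is affine-invariant and flags constants", {
  cfg <- smallConfig(seed = 6)
  fld <- simulateField(cfg)
  tab <- buildFeatureTable(fld@bands, fld@samples, 0.5)
  scr <- screenFeatures(tab, "san")
  expect_equal(scr$feature[1], "difference:green-red")
  expect_true(all(diff(abs(scr$cc[!is.na(scr$cc)])) <= 1e-12))
  expect_true(all(scr$cc >= -1 & scr$cc <= 1, na.rm = TRUE))

  # Pearson cc unchanged under affine rescale of the explained variable
  tab2 <- tab; tab2$san <- 2 * tab$san + 3
  scr2 <- screenFeatures(tab2, "san")
  expect_equal(scr2$cc, scr$cc, tolerance = 1e-12)

  # a feature perfectly linear in the explained variable has |cc| = 1
  tab3 <- tab; tab3$san <- 5 - 0.01 * tab3[["difference:green-red"]]
  scr3 <- screenFeatures(tab3, "san")
  expect_equal(abs(scr3$cc[scr3$feature == "difference:green-red"]), 1,
               tolerance = 1e-12)

  # constant feature recorded as missing, not dropped
  tabc <- tab; tabc[["ndi:green,red"]] <- 1
  scrc <- screenFeatures(tabc, "san")
  expect_true(is.na(scrc$cc[scrc$feature == "ndi:green,red"]))
  expect_equal(nrow(scrc), 28L)

  expect_error(screenFeatures(transform(tab, san = 1), "san"), "constant")
})

test_that("a SAN-independent response rarely screens above |cc| 0.5", {
  # Monte-Carlo null: n = 35 samples, explained variable pure noise
  cfg <- smallConfig(seed = 31)
  fld <- simulateField(cfg)
  tab <- buildFeatureTable(fld@bands, fld@samples, 0.5)
  set.seed(77)
  maxcc <- replicate(40, {
    tab$san <- rnorm(nrow(tab))
    max(abs(screenFeatures(tab, "san")$cc), na.rm = TRUE)
  })
  expect_gte(mean(maxcc < 0.5), 0.9)
})

test_that("the SAN model fit matches closed-form least squares", {
  tab <- data.frame(id = 1:3, san = c(7, 9, 11),
                    "difference:green-red" = 0:2, check.names = FALSE)
  m <- fitSANModel(tab)
  expect_equal(m@intercept, 7)
  expect_equal(m@slope, 2)
  expect_equal(m@rSquared, 1)

  # noise-free samples generated by inverting the estimating equation
  san <- seq(80, 198, length.out = 35)
  tab <- data.frame(san = san,
                    "difference:green-red" = (287.86 - san) / 0.046,
                    check.names = FALSE)
  m <- fitSANModel(tab)
  expect_equal(m@intercept, 287.86, tolerance = 1e-6)
  expect_equal(m@slope, -0.046, tolerance = 1e-6)
  # closed-form OLS oracle
  x <- tab[["difference:green-red"]]
  bhat <- sum((x - mean(x)) * (san - mean(san))) / sum((x - mean(x))^2)
  expect_equal(m@slope, bhat, tolerance = 1e-12)
  expect_equal(m@intercept, mean(san) - bhat * mean(x), tolerance = 1e-10)
  expect_equal(m@n, 35)

  tabz <- tab; tabz[["difference:green-red"]] <- 1
  expect_error(fitSANModel(tabz), "singular|zero variance")
})

test_that("SAN raster prediction evaluates the model per pixel", {
  model <- new("SANLinearModel", intercept = 287.86, slope = -0.046,
               rSquared = 0.45, aic = 0, n = 35,
               feature = "difference:green-red")
  g <- fieldRaster(matrix(c(1910, 0, NA), 1, 3) + 5000, 1, c(0, 1))
  r <- fieldRaster(matrix(5000, 1, 3), 1, c(0, 1))
  san <- rasterValues(predictSANRaster(model,
                                       list(green = g, red = r)))
  expect_equal(san[1, 1], 200, tolerance = 1e-9)
  expect_equal(san[1, 2], 287.86)
  expect_true(is.na(san[1, 3]))
  expect_error(predictSANRaster(model, list(green = g)), "missing band")

  # prediction + fit reproduce the latent SAN at sample points (noise-free)
  cfg <- smallConfig(noiseSdBand = 0, bandBrightnessSd = 0,
                     residueFraction = 0, noiseSdSan = 0)
  fld <- simulateField(cfg)
  tab <- buildFeatureTable(fld@bands, fld@samples, 0.15)
  m <- fitSANModel(tab)
  sanR <- predictSANRaster(m, fld@bands)
  at <- vapply(seq_len(nrow(fld@samples)), function(k)
    zonalMeanCircle(sanR, c(fld@samples$x[k], fld@samples$y[k]),
                    0.15)$mean, 0)
  expect_equal(at, fld@samples$san, tolerance = 0.02)
})

test_that("the fertility mesh map aggregates and flags the optimum range", {
  grid <- makeMeshGrid(rectangularBoundary(5, 4), 1)
  const <- function(v) fieldRaster(matrix(v, 8, 10), 0.5, c(0, 4))
  fm <- fertilityMeshMap(const(156), grid)     # mean SAN of the field
  expect_true(all(fm$san_est == 156))
  expect_true(all(fm$in_optimum))
  fm2 <- fertilityMeshMap(const(220), grid)
  expect_false(any(fm2$in_optimum))

  set.seed(14)
  r <- randomRaster(8, 10, cellSize = 0.5, origin = c(0, 4))
  fm3 <- fertilityMeshMap(r, grid)
  expect_equal(fm3$san_est, oracleMeshMeans(r, grid)$mean,
               tolerance = 1e-12)
})
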