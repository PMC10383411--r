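test_that("raster subtraction handles values, nodata and misalignment", {
  a <- fieldRaster(matrix(5.3, 2, 2), 1, c(0, 2))
  b <- fieldRaster(matrix(4.7, 2, 2), 1, c(0, 2))
  expect_equal(rasterValues(rasterSubtract(a, b)),
               matrix(0.6, 2, 2), tolerance = 1e-12)
  expect_true(all(rasterValues(rasterSubtract(a, a)) == 0))

  a@values[1, 2] <- NA
  d <- rasterSubtract(a, b)
  expect_true(is.na(rasterValues(d)[1, 2]))
  expect_false(anyNA(rasterValues(d)[2, ]))

  shifted <- fieldRaster(matrix(4.7, 2, 2), 1, c(0.5, 2))
  expect_error(rasterSubtract(a, shifted), "not aligned")
  expect_error(a - fieldRaster(matrix(1, 3, 2), 1, c(0, 3)), "not aligned")

  # (a - b) + b = a on all valid pixels, and via the Arith group generic
  set.seed(11)
  for (k in 1:5) {
    x <- randomRaster(7, 9, naFrac = 0.1)
    y <- randomRaster(7, 9, cellSize = 0.5, origin = c(0, 3.5))
    back <- (x - y) + y
    ok <- !nodataMask(x)
    expect_equal(rasterValues(back)[ok], rasterValues(x)[ok],
                 tolerance = 1e-12)
  }
})

test_that("mesh grid matches the closed form and a brute-force oracle", {
  g <- makeMeshGrid(rectangularBoundary(55, 80), 1, edgeWidth = 4)
  cells <- meshCells(g)
  expect_equal(nrow(cells), 4400L)
  expect_equal(sum(!cells$is_edge), (55 - 8) * (80 - 8))  # 3384
  expect_equal(sum(cells$is_edge) + sum(!cells$is_edge), nrow(cells))
  expect_equal(sum(!cells$is_edge) / nrow(cells), 3384 / 4400)

  # brute-force rectangle-membership count over the bounding box
  cnt <- 0L
  for (cx in seq(0.5, 54.5, by = 1)) for (cy in seq(0.5, 79.5, by = 1))
    if (cx > 0 && cx < 55 && cy > 0 && cy < 80) cnt <- cnt + 1L
  expect_equal(nrow(cells), cnt)

  # no edge flags at zero edge width
  g0 <- makeMeshGrid(rectangularBoundary(10, 10), 1, edgeWidth = 0)
  expect_false(any(meshCells(g0)$is_edge))

  # non-rectangular boundary against an independent barycentric oracle
  tri <- fieldBoundary(cbind(c(0, 12, 0), c(0, 0, 9)))
  gt <- makeMeshGrid(tri, 1)
  ct <- meshCells(gt)
  want <- outer(seq(0.5, 11.5), seq(0.5, 8.5), function(px, py)
    oracleInTriangle(px, py, c(0, 0), c(12, 0), c(0, 9)))
  expect_equal(nrow(ct), sum(want))
  expect_true(all(oracleInTriangle(ct$x, ct$y, c(0, 0), c(12, 0), c(0, 9))))

  expect_error(makeMeshGrid(rectangularBoundary(10, 10), -1), "cellSize")
  expect_error(fieldBoundary(cbind(c(0, 1, 2), c(0, 1, 2))), "degenerate")
})

test_that("buffer-circle zonal means equal the exhaustive oracle", {
  r <- fieldRaster(matrix(3.25, 10, 10), 0.5, c(0, 5))
  expect_equal(zonalMeanCircle(r, c(2.5, 2.5), 1)$mean, 3.25)

  set.seed(23)
  for (k in 1:8) {
    r <- randomRaster(30, 40, cellSize = 0.25, origin = c(0, 7.5),
                      naFrac = 0.05)
    centre <- c(runif(1, 1, 9), runif(1, 1, 6.5))
    radius <- runif(1, 0.3, 1.5)
    got <- zonalMeanCircle(r, centre, radius)
    want <- oracleCircleMean(r, centre, radius)
    expect_equal(got$mean, unname(want["mean"]), tolerance = 1e-12)
    expect_equal(got$n, unname(want["n"]))
  }

  # invariance to translating raster and zone by the same offset
  r <- randomRaster(20, 20, cellSize = 0.3, origin = c(0, 6))
  r2 <- fieldRaster(rasterValues(r), 0.3, c(100, 6 - 50))
  z1 <- zonalMeanCircle(r, c(3, 3), 0.8)
  z2 <- zonalMeanCircle(r2, c(103, -47), 0.8)
  expect_equal(z1, z2)

  expect_error(zonalMeanCircle(r, c(50, 50), 0.5), "empty zone")
  allna <- fieldRaster(matrix(NA_real_, 5, 5), 1, c(0, 5))
  expect_error(zonalMeanCircle(allna, c(2.5, 2.5), 1), "empty zone")
})

test_that("mesh zonal means equal the exhaustive assignment oracle", {
  bnd <- rectangularBoundary(5, 4)
  grid <- makeMeshGrid(bnd, 1)
  rconst <- fieldRaster(matrix(7.5, 8, 10), 0.5, c(0, 4))
  z <- zonalMeanMesh(rconst, grid)
  expect_true(all(z$mean == 7.5))
  expect_true(all(z$n == 4L))   # 1 m cells on 0.5 m pixels: 4 centres each

  set.seed(31)
  for (k in 1:4) {
    r <- randomRaster(16, 20, cellSize = 0.25, origin = c(0, 4),
                      naFrac = 0.1)
    got <- zonalMeanMesh(r, grid)
    want <- oracleMeshMeans(r, grid)
    expect_equal(got$mean, want$mean, tolerance = 1e-12)
    expect_equal(got$n, want$n)
  }

  # a fully-nodata cell is flagged missing
  v <- matrix(1, 8, 10)
  v[1:2, 1:2] <- NA   # covers cell [0,1) x [3,4)
  z <- zonalMeanMesh(fieldRaster(v, 0.5, c(0, 4)), grid)
  miss <- meshCells(grid)$x < 1 & meshCells(grid)$y > 3
  expect_true(all(z$missing[miss]))
  expect_true(all(!z$missing[!miss]))
})

test_that("ascii-grid and WKT round trips preserve everything", {
  set.seed(7)
  r <- randomRaster(13, 9, cellSize = 0.051, origin = c(3.2, 41.7),
                    naFrac = 0.15)
  f <- tempfile(fileext = ".asc")
  writeAsciiGrid(r, f)
  r2 <- readAsciiGrid(f)
  expect_identical(rasterValues(r2), rasterValues(r))
  expect_equal(cellSize(r2), cellSize(r))
  expect_equal(rasterOrigin(r2), rasterOrigin(r))
  expect_identical(nodataMask(r2), nodataMask(r))

  bad <- tempfile()
  writeLines(c("1 2 3", "4 5 6"), bad)
  expect_error(readAsciiGrid(bad), "georeferenced")
  expect_error(readAsciiGrid(tempfile()), "not found")

  b <- fieldBoundary(cbind(c(0, 55, 55, 0), c(0, 0, 80, 80)))
  fw <- tempfile(fileext = ".wkt")
  writeBoundaryWKT(b, fw)
  b2 <- readBoundaryWKT(fw)
  expect_equal(b2@vertices, b@vertices, ignore_attr = TRUE)
})
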