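# Shared fixtures and independent brute-force oracles. The oracles use plain
# double loops over pixel centres so they share no code path with the
# vectorised implementations they check.

`%||%` <- function(a, b) if (is.null(a)) b else a

smallConfig <- function(seed = 42, ...) {
  fieldConfig(width = 20, height = 28, bandCellSize = 0.2,
              elevationCellSize = 0.2, seed = seed, ...)
}

randomRaster <- function(nr, nc, cellSize = 0.5, origin = c(0, nr * cellSize),
                         naFrac = 0) {
  m <- matrix(rnorm(nr * nc), nr, nc)
  if (naFrac > 0) m[sample(length(m), ceiling(naFrac * length(m)))] <- NA
  fieldRaster(m, cellSize, origin)
}

# exhaustive pixel-centre mean over a circle
oracleCircleMean <- function(r, centre, radius) {
  v <- rasterValues(r); cs <- cellSize(r); o <- rasterOrigin(r)
  tot <- 0; n <- 0
  for (i in seq_len(nrow(v))) for (j in seq_len(ncol(v))) {
    px <- o[1] + (j - 0.5) * cs
    py <- o[2] - (i - 0.5) * cs
    if ((px - centre[1])^2 + (py - centre[2])^2 <= radius^2 &&
        !is.na(v[i, j])) {
      tot <- tot + v[i, j]; n <- n + 1
    }
  }
  if (n == 0) stop("oracle: empty zone")
  c(mean = tot / n, n = n)
}

# exhaustive pixel-to-cell assignment over half-open mesh cells
oracleMeshMeans <- function(r, grid) {
  v <- rasterValues(r); cs <- cellSize(r); o <- rasterOrigin(r)
  cells <- meshCells(grid); gcs <- cellSize(grid)
  anchor <- grid@anchor
  tot <- rep(0, nrow(cells)); n <- rep(0L, nrow(cells))
  for (i in seq_len(nrow(v))) for (j in seq_len(ncol(v))) {
    if (is.na(v[i, j])) next
    px <- o[1] + (j - 0.5) * cs
    py <- o[2] - (i - 0.5) * cs
    for (k in seq_len(nrow(cells))) {
      x0 <- anchor[1] + cells$ix[k] * gcs
      y0 <- anchor[2] + cells$iy[k] * gcs
      if (px >= x0 && px < x0 + gcs && py >= y0 && py < y0 + gcs) {
        tot[k] <- tot[k] + v[i, j]; n[k] <- n[k] + 1L
        break
      }
    }
  }
  data.frame(mesh_id = cells$mesh_id,
             mean = ifelse(n > 0, tot / pmax(n, 1), NA_real_), n = n)
}

# barycentric point-in-triangle test (independent of ray casting)
oracleInTriangle <- function(px, py, a, b, c) {
  d <- (b[2] - c[2]) * (a[1] - c[1]) + (c[1] - b[1]) * (a[2] - c[2])
  l1 <- ((b[2] - c[2]) * (px - c[1]) + (c[1] - b[1]) * (py - c[2])) / d
  l2 <- ((c[2] - a[2]) * (px - c[1]) + (a[1] - c[1]) * (py - c[2])) / d
  l3 <- 1 - l1 - l2
  l1 >= 0 & l2 >= 0 & l3 >= 0
}
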