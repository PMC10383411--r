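# Raster data model, algebra, zonal statistics, mesh construction, file I/O.

#' Create a FieldRaster
#'
#' @param values numeric matrix; rows run north to south, columns west to
#'   east. \code{NA} marks nodata.
#' @param cellSize metres per pixel
#' @param origin planar (x, y) of the top-left corner, metres
#' @return a \linkS4class{FieldRaster}
#' @examples
#' r <- fieldRaster(matrix(1:6, 2, 3), cellSize = 0.5, origin = c(0, 1))
#' cellSize(r)
#' @export
fieldRaster <- function(values, cellSize, origin = c(0, 0)) {
  storage.mode(values) <- "double"
  new("FieldRaster", values = values, cellSize = as.numeric(cellSize),
      origin = as.numeric(origin))
}

#' Pixel-centre coordinates of a raster
#'
#' @param x a FieldRaster
#' @return list with \code{x} (per column) and \code{y} (per row) centre
#'   coordinates in metres
#' @export
pixelCentres <- function(x) {
  stopifnot(is(x, "FieldRaster"))
  d <- dim(x@values)
  list(x = x@origin[1] + (seq_len(d[2]) - 0.5) * x@cellSize,
       y = x@origin[2] - (seq_len(d[1]) - 0.5) * x@cellSize)
}

.stopifnotAligned <- function(a, b) {
  if (!identical(dim(a@values), dim(b@values)) ||
      abs(a@cellSize - b@cellSize) > 1e-9 ||
      any(abs(a@origin - b@origin) > 1e-9))
    stop("rasters are not aligned: identical shape, origin and cell size ",
         "are required", call. = FALSE)
  invisible(TRUE)
}

#' Raster subtraction
#'
#' Per-pixel \code{a - b} on aligned grids; the canopy height model is the
#' special case DSM - DTM. Nodata propagates: the result is nodata wherever
#' either input is.
#'
#' @param a,b aligned FieldRasters
#' @return a FieldRaster
#' @export
rasterSubtract <- function(a, b) {
  .stopifnotAligned(a, b)
  fieldRaster(a@values - b@values, a@cellSize, a@origin)
}

#' @describeIn FieldRaster-class arithmetic between aligned rasters, or
#'   between a raster and a scalar; nodata propagates
#' @param e1,e2 FieldRaster or numeric scalar operands
#' @export
setMethod("Arith", signature("FieldRaster", "FieldRaster"), function(e1, e2) {
  .stopifnotAligned(e1, e2)
  fieldRaster(callGeneric(e1@values, e2@values), e1@cellSize, e1@origin)
})

#' @rdname FieldRaster-class
#' @export
setMethod("Arith", signature("FieldRaster", "numeric"), function(e1, e2) {
  fieldRaster(callGeneric(e1@values, e2), e1@cellSize, e1@origin)
})

#' @rdname FieldRaster-class
#' @export
setMethod("Arith", signature("numeric", "FieldRaster"), function(e1, e2) {
  fieldRaster(callGeneric(e1, e2@values), e2@cellSize, e2@origin)
})

# ---- boundary geometry ------------------------------------------------------

# signed shoelace area; positive for counter-clockwise vertex order
.shoelace <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Create a field boundary polygon
#'
#' @param vertices two-column matrix of (x, y) in metres; the closing vertex
#'   may be repeated or omitted
#' @return a \linkS4class{FieldBoundary}
#' @export
fieldBoundary <- function(vertices) {
  vertices <- as.matrix(vertices)
  n <- nrow(vertices)
  if (n >= 2L && all(vertices[1, ] == vertices[n, ]))
    vertices <- vertices[-n, , drop = FALSE]
  new("FieldBoundary", vertices = vertices)
}

#' Rectangular field boundary
#'
#' @param width,height extent in metres (the reference field is 55 x 80 m)
#' @param origin (x, y) of the minimum (south-west) corner
#' @export
rectangularBoundary <- function(width, height, origin = c(0, 0)) {
  fieldBoundary(cbind(
    x = origin[1] + c(0, width, width, 0),
    y = origin[2] + c(0, 0, height, height)))
}

# even-odd ray casting, vectorised over points; boundary points count inside
.pointInPolygon <- function(px, py, verts) {
  n <- nrow(verts)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- verts[i, 1]; yi <- verts[i, 2]
    xj <- verts[j, 1]; yj <- verts[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# minimum Euclidean distance from points to the closed polygon polyline
.distToBoundary <- function(px, py, verts) {
  n <- nrow(verts)
  d2 <- rep(Inf, length(px))
  j <- n
  for (i in seq_len(n)) {
    ax <- verts[j, 1]; ay <- verts[j, 2]
    bx <- verts[i, 1]; by <- verts[i, 2]
    vx <- bx - ax; vy <- by - ay
    len2 <- vx * vx + vy * vy
    t <- if (len2 > 0) pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / len2))
         else 0
    dx <- px - (ax + t * vx); dy <- py - (ay + t * vy)
    d2 <- pmin(d2, dx * dx + dy * dy)
    j <- i
  }
  sqrt(d2)
}

#' Bounding box of a boundary
#' @param boundary a FieldBoundary
#' @return list with xmin, xmax, ymin, ymax
#' @export
boundaryBBox <- function(boundary) {
  v <- boundary@vertices
  list(xmin = min(v[, 1]), xmax = max(v[, 1]),
       ymin = min(v[, 2]), ymax = max(v[, 2]))
}

# ---- mesh grid --------------------------------------------------------------

#' Build the analysis mesh over a field
#'
#' Tiles the boundary's bounding box with half-open square cells
#' \code{[x, x + cellSize) x [y, y + cellSize)} anchored at the bounding-box
#' minimum corner. A cell belongs to the grid iff its centre lies inside the
#' boundary; it is flagged \code{is_edge} iff the centre lies strictly within
#' \code{edgeWidth} of the boundary polyline. For a W x H rectangle with
#' integer dimensions and edge width e, the inside cells form the
#' (W - 2e) x (H - 2e) interior rectangle.
#'
#' @param boundary a \linkS4class{FieldBoundary}
#' @param cellSize cell side, metres (default 1 m)
#' @param edgeWidth edge-zone width, metres (default 0; the reference
#'   analysis uses 4 m)
#' @return a \linkS4class{MeshGrid}
#' @examples
#' g <- makeMeshGrid(rectangularBoundary(55, 80), 1, edgeWidth = 4)
#' nrow(meshCells(g))            # 4400
#' sum(!meshCells(g)$is_edge)    # 3384 inside cells
#' @export
makeMeshGrid <- function(boundary, cellSize = 1, edgeWidth = 0) {
  stopifnot(is(boundary, "FieldBoundary"))
  if (cellSize <= 0) stop("'cellSize' must be > 0", call. = FALSE)
  if (edgeWidth < 0) stop("'edgeWidth' must be >= 0", call. = FALSE)
  bb <- boundaryBBox(boundary)
  nx <- ceiling((bb$xmax - bb$xmin) / cellSize - 1e-9)
  ny <- ceiling((bb$ymax - bb$ymin) / cellSize - 1e-9)
  if (nx < 1L || ny < 1L) stop("degenerate boundary", call. = FALSE)
  ix <- rep(seq_len(nx) - 1L, times = ny)
  iy <- rep(seq_len(ny) - 1L, each = nx)
  cx <- bb$xmin + (ix + 0.5) * cellSize
  cy <- bb$ymin + (iy + 0.5) * cellSize
  keep <- .pointInPolygon(cx, cy, boundary@vertices)
  ix <- ix[keep]; iy <- iy[keep]; cx <- cx[keep]; cy <- cy[keep]
  isEdge <- if (edgeWidth > 0)
    .distToBoundary(cx, cy, boundary@vertices) < edgeWidth
  else rep(FALSE, length(cx))
  cells <- data.frame(mesh_id = seq_along(cx), ix = ix, iy = iy,
                      x = cx, y = cy, is_edge = isEdge)
  new("MeshGrid", cellSize = as.numeric(cellSize),
      edgeWidth = as.numeric(edgeWidth), cells = cells,
      anchor = c(bb$xmin, bb$ymin))
}

# ---- zonal statistics -------------------------------------------------------

#' Mean raster value over a buffer circle
#'
#' Mean of the non-nodata pixels whose centres lie within \code{radius} of the
#' buffer centre (pixel-centre membership, the standard GIS zone-statistics
#' rule). Reference radii are 0.15, 0.25 and 0.5 m around survey and soil
#' sampling points.
#'
#' @param x a FieldRaster
#' @param centre (x, y) of the buffer centre, metres
#' @param radius buffer radius, metres (> 0)
#' @return list with \code{mean} and the contributing pixel count \code{n}
#' @export
zonalMeanCircle <- function(x, centre, radius) {
  stopifnot(is(x, "FieldRaster"), radius > 0, length(centre) == 2L)
  pc <- pixelCentres(x)
  js <- which(pc$x >= centre[1] - radius & pc$x <= centre[1] + radius)
  is <- which(pc$y >= centre[2] - radius & pc$y <= centre[2] + radius)
  if (!length(js) || !length(is))
    stop("empty zone: no pixel centre falls inside the buffer", call. = FALSE)
  dx <- pc$x[js] - centre[1]
  dy <- pc$y[is] - centre[2]
  inC <- outer(dy^2, dx^2, "+") <= radius^2
  vals <- x@values[is, js, drop = FALSE][inC]
  vals <- vals[!is.na(vals)]
  if (!length(vals))
    stop("empty zone: no valid (non-nodata) pixel inside the buffer",
         call. = FALSE)
  list(mean = mean(vals), n = length(vals))
}

#' Per-cell mean raster values over a mesh grid
#'
#' Assigns every non-nodata pixel centre to the half-open mesh cell containing
#' it and averages per cell. Cells with no contributing pixel are flagged
#' missing (mean \code{NA}).
#'
#' @param x a FieldRaster sharing the mesh's coordinate frame
#' @param grid a \linkS4class{MeshGrid}
#' @return data.frame: mesh_id, mean, n, missing
#' @export
zonalMeanMesh <- function(x, grid) {
  stopifnot(is(x, "FieldRaster"), is(grid, "MeshGrid"))
  pc <- pixelCentres(x)
  d <- dim(x@values)
  px <- rep(pc$x, each = d[1])
  py <- rep(pc$y, times = d[2])
  ix <- floor((px - grid@anchor[1]) / grid@cellSize)
  iy <- floor((py - grid@anchor[2]) / grid@cellSize)
  key <- paste(ix, iy)
  cellKey <- paste(grid@cells$ix, grid@cells$iy)
  idx <- match(key, cellKey)
  v <- as.vector(x@values)
  ok <- !is.na(idx) & !is.na(v)
  sums <- rowsum(v[ok], idx[ok])
  cnts <- rowsum(rep(1, sum(ok)), idx[ok])
  out <- data.frame(mesh_id = grid@cells$mesh_id,
                    mean = NA_real_, n = 0L)
  rid <- as.integer(rownames(sums))
  out$mean[rid] <- sums[, 1] / cnts[, 1]
  out$n[rid] <- as.integer(cnts[, 1])
  out$missing <- out$n == 0L
  out
}

# ---- file I/O ---------------------------------------------------------------

#' Read / write a raster as an ESRI ASCII grid
#'
#' Plain-text georeferenced single-band raster format (ncols/nrows/
#' xllcorner/yllcorner/cellsize/NODATA_value header, rows north to south).
#' The round trip preserves values, nodata, origin and cell size exactly
#' (values are written with 17 significant digits).
#'
#' @param path file path (conventionally .asc)
#' @return \code{readAsciiGrid} returns a \linkS4class{FieldRaster};
#'   \code{writeAsciiGrid} returns \code{path} invisibly.
#' @export
readAsciiGrid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  head <- readLines(path, n = 6L)
  kv <- strsplit(trimws(head), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1L))
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!identical(keys, need))
    stop("not a georeferenced ASCII grid (bad header): ", path,
         call. = FALSE)
  h <- as.numeric(vapply(kv, `[`, "", 2L))
  names(h) <- keys
  vals <- scan(path, skip = 6L, quiet = TRUE)
  if (length(vals) != h["ncols"] * h["nrows"])
    stop("corrupt grid: expected ", h["ncols"] * h["nrows"], " values",
         call. = FALSE)
  m <- matrix(vals, nrow = h["nrows"], ncol = h["ncols"], byrow = TRUE)
  m[m == h["nodata_value"]] <- NA_real_
  fieldRaster(m, h["cellsize"],
              origin = c(h["xllcorner"], h["yllcorner"] + h["nrows"] * h["cellsize"]))
}

#' @rdname readAsciiGrid
#' @param x a FieldRaster
#' @export
writeAsciiGrid <- function(x, path) {
  stopifnot(is(x, "FieldRaster"))
  d <- dim(x@values)
  fin <- x@values[is.finite(x@values)]
  nodata <- if (length(fin)) floor(min(fin)) - 9999 else -9999
  m <- x@values
  m[is.na(m)] <- nodata
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", d[2]),
    paste("nrows", d[1]),
    paste("xllcorner", sprintf("%.17g", x@origin[1])),
    paste("yllcorner", sprintf("%.17g", x@origin[2] - d[1] * x@cellSize)),
    paste("cellsize", sprintf("%.17g", x@cellSize)),
    paste("NODATA_value", sprintf("%.17g", nodata))), con)
  for (i in seq_len(d[1]))
    writeLines(paste(sprintf("%.17g", m[i, ]), collapse = " "), con)
  invisible(path)
}

#' Read / write a field boundary as WKT
#'
#' Supports the single-ring \code{POLYGON ((x y, ...))} form.
#'
#' @param path file path
#' @return \code{readBoundaryWKT} returns a \linkS4class{FieldBoundary}
#' @export
readBoundaryWKT <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = " ")
  m <- regmatches(txt, regexpr("POLYGON\\s*\\(\\(([^)]*)\\)\\)", txt))
  if (!length(m)) stop("no WKT POLYGON found in ", path, call. = FALSE)
  inner <- sub(".*\\(\\(", "", sub("\\)\\).*", "", m))
  pairs <- strsplit(trimws(strsplit(inner, ",")[[1]]), "\\s+")
  fieldBoundary(do.call(rbind, lapply(pairs, function(p) as.numeric(p[1:2]))))
}

#' @rdname readBoundaryWKT
#' @param boundary a FieldBoundary
#' @export
writeBoundaryWKT <- function(boundary, path) {
  v <- boundary@vertices
  v <- rbind(v, v[1, ])
  writeLines(sprintf("POLYGON ((%s))", paste(
    sprintf("%.17g %.17g", v[, 1], v[, 2]), collapse = ", ")), path)
  invisible(path)
}
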