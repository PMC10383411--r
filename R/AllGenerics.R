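#' @rdname FieldRaster-class
#' @param object,x a FieldRaster
#' @export
setGeneric("rasterValues", function(x) standardGeneric("rasterValues"))

#' @rdname FieldRaster-class
#' @export
setGeneric("cellSize", function(x) standardGeneric("cellSize"))

#' @rdname FieldRaster-class
#' @export
setGeneric("rasterOrigin", function(x) standardGeneric("rasterOrigin"))

#' @rdname FieldRaster-class
#' @export
setGeneric("nodataMask", function(x) standardGeneric("nodataMask"))

#' @rdname MeshGrid-class
#' @param x a MeshGrid
#' @export
setGeneric("meshCells", function(x) standardGeneric("meshCells"))

setMethod("rasterValues", "FieldRaster", function(x) x@values)
setMethod("cellSize", "FieldRaster", function(x) x@cellSize)
setMethod("cellSize", "MeshGrid", function(x) x@cellSize)
setMethod("rasterOrigin", "FieldRaster", function(x) x@origin)
setMethod("nodataMask", "FieldRaster", function(x) is.na(x@values))
setMethod("meshCells", "MeshGrid", function(x) x@cells)

setMethod("dim", "FieldRaster", function(x) dim(x@values))

setMethod("show", "FieldRaster", function(object) {
  d <- dim(object@values)
  v <- object@values[!is.na(object@values)]
  cat("FieldRaster: ", d[1], " x ", d[2], " pixels @ ",
      format(object@cellSize), " m\n", sep = "")
  cat("  origin (top-left): (", format(object@origin[1]), ", ",
      format(object@origin[2]), ") m\n", sep = "")
  if (length(v))
    cat("  values: [", format(min(v), digits = 5), ", ",
        format(max(v), digits = 5), "], nodata: ",
        sum(is.na(object@values)), " px\n", sep = "")
  else cat("  values: all nodata\n")
  invisible(NULL)
})

setMethod("show", "FieldBoundary", function(object) {
  bb <- apply(object@vertices, 2, range)
  cat("FieldBoundary: ", nrow(object@vertices), " vertices, area ",
      format(abs(.shoelace(object@vertices)), digits = 6), " m^2, bbox [",
      format(bb[1, 1]), ", ", format(bb[2, 1]), "] x [",
      format(bb[1, 2]), ", ", format(bb[2, 2]), "]\n", sep = "")
  invisible(NULL)
})

setMethod("show", "MeshGrid", function(object) {
  cat("MeshGrid: ", nrow(object@cells), " cells of ",
      format(object@cellSize), " m (",
      sum(!object@cells$is_edge), " inside, ", sum(object@cells$is_edge),
      " edge at edge width ", format(object@edgeWidth), " m)\n", sep = "")
  invisible(NULL)
})

setMethod("show", "FieldConfig", function(object) {
  cat("FieldConfig: ", format(object@width), " x ", format(object@height),
      " m field, band GSD ", format(object@bandCellSize),
      " m, elevation GSD ", format(object@elevationCellSize), " m\n",
      "  SAN in [", format(object@sanRange[1]), ", ",
      format(object@sanRange[2]), "] mg N kg^-1, ",
      object@nSamplesA + object@nSamplesB, " soil samples, seed ",
      format(object@seed), "\n", sep = "")
  invisible(NULL)
})

setMethod("show", "SyntheticField", function(object) {
  cat("SyntheticField (", format(object@config@width), " x ",
      format(object@config@height), " m):\n", sep = "")
  cat("  elevation rasters: dtm, dsmMax, dsmHarvest (",
      paste(dim(object@dtm@values), collapse = " x "), " px)\n", sep = "")
  cat("  bands: ", paste(names(object@bands), collapse = ", "), " (",
      paste(dim(object@bands$green@values), collapse = " x "),
      " px)\n", sep = "")
  cat("  soil samples: ", nrow(object@samples), "\n", sep = "")
  invisible(NULL)
})

setMethod("show", "SANLinearModel", function(object) {
  cat("SANLinearModel on ", object@feature, " (n = ", object@n, ")\n",
      "  SAN = ", format(object@intercept, digits = 6),
      ifelse(object@slope < 0, " - ", " + "),
      format(abs(object@slope), digits = 4), " x (", object@feature, ")\n",
      "  R^2 = ", format(object@rSquared, digits = 3),
      ", AIC = ", format(object@aic, digits = 5), "\n", sep = "")
  invisible(NULL)
})

setMethod("show", "SoilLineClassifier", function(object) {
  cat("SoilLineClassifier (logistic, 4 bands):\n  alpha = ",
      format(object@alpha, digits = 5), "\n  betas: ",
      paste(names(object@betas), format(object@betas, digits = 4),
            sep = " = ", collapse = ", "), "\n  ",
      if (object@separated) "complete separation detected"
      else if (object@converged)
        paste0("converged in ", object@nIter, " iterations")
      else paste0("NOT converged after ", object@nIter, " iterations"),
      "\n", sep = "")
  invisible(NULL)
})

setMethod("show", "SoilLine", function(object) {
  cat("SoilLine: NIR = ", format(object@intercept, digits = 6), " + ",
      format(object@slope, digits = 5), " x red  (rmse ",
      format(object@rmse, digits = 4), " DN, n = ", object@n, ")\n",
      sep = "")
  invisible(NULL)
})
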