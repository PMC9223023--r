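#' @rdname LightRaster-class
#' @param object,x an object.
#' @export
setGeneric("rasterValues", function(x) standardGeneric("rasterValues"))

#' @rdname LightRaster-class
#' @export
setGeneric("nodataMask", function(x) standardGeneric("nodataMask"))

#' @rdname LightRaster-class
#' @export
setGeneric("geoTransform", function(x) standardGeneric("geoTransform"))

#' @rdname LightRaster-class
#' @export
setGeneric("crsLabel", function(x) standardGeneric("crsLabel"))

#' @rdname ZonePolygons-class
#' @export
setGeneric("zoneIds", function(x) standardGeneric("zoneIds"))

#' @rdname ZonePolygons-class
#' @export
setGeneric("zoneGeometry", function(x) standardGeneric("zoneGeometry"))

#' @rdname ZonePolygons-class
#' @export
setGeneric("zoneLevel", function(x) standardGeneric("zoneLevel"))

#' @rdname SpatialWeights-class
#' @export
setGeneric("neighborList", function(x) standardGeneric("neighborList"))

#' @rdname SpatialWeights-class
#' @export
setGeneric("weightList", function(x) standardGeneric("weightList"))

#' @rdname SpatialWeights-class
#' @export
setGeneric("weightsMatrix", function(x) standardGeneric("weightsMatrix"))

#' @rdname SpatialWeights-class
#' @export
setGeneric("cardinality", function(x) standardGeneric("cardinality"))

setMethod("rasterValues", "LightRaster", function(x) x@values)
setMethod("nodataMask", "LightRaster", function(x) x@nodata)
setMethod("geoTransform", "LightRaster", function(x) x@geotransform)
setMethod("crsLabel", "LightRaster", function(x) x@crs)

setMethod("zoneIds", "ZonePolygons", function(x) x@zoneId)
setMethod("zoneGeometry", "ZonePolygons", function(x) x@geometry)
setMethod("zoneLevel", "ZonePolygons", function(x) x@level)

setMethod("neighborList", "SpatialWeights", function(x) x@neighbors)
setMethod("weightList", "SpatialWeights", function(x) x@weights)
setMethod("cardinality", "SpatialWeights",
          function(x) vapply(x@neighbors, length, integer(1)))

#' @describeIn SpatialWeights-class dense n x n weight matrix (small n).
setMethod("weightsMatrix", "SpatialWeights", function(x) {
  n <- length(x@ids)
  W <- matrix(0, n, n, dimnames = list(x@ids, x@ids))
  for (i in seq_len(n)) W[i, x@neighbors[[i]]] <- x@weights[[i]]
  W
})

setMethod("show", "LightRaster", function(object) {
  d <- dim(object@values)
  cat("LightRaster:", d[1], "x", d[2], "cells |", sum(object@nodata),
      "nodata | crs:", object@crs,
      if (object@integerDN) "| integer DN\n" else "| fractional DN\n")
  gt <- object@geotransform
  cat("  origin (", gt[1], ",", gt[4], ") cell ", gt[2], "x", -gt[6], "\n")
})

setMethod("show", "ZonePolygons", function(object) {
  cat("ZonePolygons:", length(object@zoneId), "zones | level:",
      object@level, "\n")
  if (length(object@zoneId))
    cat("  ids:", paste(head(object@zoneId, 5), collapse = ", "),
        if (length(object@zoneId) > 5) "...", "\n")
})

setMethod("show", "SpatialWeights", function(object) {
  k <- cardinality(object)
  cat("SpatialWeights:", length(object@ids), "units |",
      object@standardization, "standardization | mean neighbors:",
      round(mean(k), 2), "\n")
  if (any(k == 0))
    cat("  islands:", sum(k == 0), "unit(s) with no neighbors\n")
})

setMethod("show", "CurveFit", function(object) {
  cf <- object@coefficients
  cat("CurveFit:", object@model, "| n =", object@nObs, "\n")
  cat("  coefficients:",
      paste(names(cf), signif(cf, 6), sep = "=", collapse = " "), "\n")
  cat("  R2 (fitting scale):", round(object@r2Transformed, 4),
      "| R2 (original scale):", round(object@r2Original, 4), "\n")
})

setMethod("show", "GlobalMoran", function(object) {
  cat("Global Moran's I =", round(object@I, 4),
      "| E[I] =", round(object@expectation, 4),
      "| z =", round(object@z, 4), "\n")
  if (!is.na(object@pseudoP))
    cat("  pseudo p =", signif(object@pseudoP, 4), "(",
        object@nPermutations, "permutations )\n")
})
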