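#' @import methods
#' @importFrom stats lm coef rnorm rpois runif var sd cor cor.test pnorm
#'   setNames complete.cases
#' @importFrom utils read.csv write.csv head
NULL

#' LightRaster: a gridded nighttime-light brightness image
#'
#' Container for a single-band brightness raster of digital-number (DN)
#' values together with a nodata mask and georeferencing. DMSP/OLS-style
#' imagery carries integer DN in [0, 63]; after cubic resampling values may
#' be fractional (still clamped to [0, 63]), so the integer invariant is
#' enforced only while \code{integerDN} is \code{TRUE}.
#'
#' The geotransform follows the GDAL convention
#' \code{c(x0, dx, 0, y0, 0, -dy)}: the (row r, col c) cell center sits at
#' \code{x = x0 + (c - 0.5) * dx}, \code{y = y0 - (r - 0.5) * dy}.
#' Rotated grids are not supported.
#'
#' @slot values numeric matrix of DN values (rows = north to south).
#' @slot nodata logical matrix, same shape; \code{TRUE} marks missing cells.
#' @slot geotransform numeric(6), GDAL-style affine, no rotation terms.
#' @slot crs character tag naming the coordinate system (see
#'   \code{\link{crsIsKnown}}).
#' @slot integerDN logical; when \code{TRUE}, validity requires all valid
#'   cells to hold integers in [0, 63].
#' @export
setClass("LightRaster",
  representation(
    values = "matrix",
    nodata = "matrix",
    geotransform = "numeric",
    crs = "character",
    integerDN = "logical"
  ),
  prototype(
    geotransform = c(0, 1, 0, 0, 0, -1),
    crs = "cartesian",
    integerDN = TRUE
  )
)

setValidity("LightRaster", function(object) {
  msg <- character()
  v <- object@values
  m <- object@nodata
  if (!is.numeric(v)) msg <- c(msg, "values must be numeric")
  if (!identical(dim(v), dim(m)))
    msg <- c(msg, "values and nodata mask must have identical dimensions")
  if (!is.logical(m)) msg <- c(msg, "nodata mask must be logical")
  gt <- object@geotransform
  if (length(gt) != 6 || gt[3] != 0 || gt[5] != 0)
    msg <- c(msg, "geotransform must be length 6 with zero rotation terms")
  if (length(gt) == 6 && (gt[2] <= 0 || gt[6] >= 0))
    msg <- c(msg, "geotransform must have dx > 0 and dy < 0")
  ok <- !m
  if (any(ok)) {
    vv <- v[ok]
    if (anyNA(vv)) msg <- c(msg, "valid cells must not be NA")
    else {
      if (isTRUE(object@integerDN) &&
          (any(vv != round(vv)) || any(vv < 0) || any(vv > 63)))
        msg <- c(msg, "valid DN cells must be integers in [0, 63]")
      if (!isTRUE(object@integerDN) && (any(vv < 0) || any(vv > 63)))
        msg <- c(msg, "valid DN cells must lie in [0, 63]")
    }
  }
  if (length(msg)) msg else TRUE
})

#' ZonePolygons: polygonal statistical zones with stable identifiers
#'
#' A set of polygons (optionally multi-part) in the coordinate frame of an
#' accompanying raster. Each zone has a unique textual identifier within
#' its nesting level (\code{"province"} or \code{"city"}).
#'
#' @slot zoneId character vector of unique zone identifiers.
#' @slot geometry list, one element per zone; each element is a list of
#'   rings, each ring a closed two-column (x, y) coordinate matrix.
#' @slot level character, \code{"province"} or \code{"city"}.
#' @export
setClass("ZonePolygons",
  representation(
    zoneId = "character",
    geometry = "list",
    level = "character"
  ),
  prototype(level = "city")
)

setValidity("ZonePolygons", function(object) {
  msg <- character()
  if (length(object@zoneId) != length(object@geometry))
    msg <- c(msg, "zoneId and geometry lengths differ")
  if (anyDuplicated(object@zoneId))
    msg <- c(msg, "zone identifiers must be unique within a level")
  if (!object@level %in% c("province", "city"))
    msg <- c(msg, "level must be 'province' or 'city'")
  for (g in object@geometry) {
    if (!is.list(g) || !length(g)) {
      msg <- c(msg, "each geometry must be a non-empty list of rings")
      break
    }
    for (r in g) {
      if (!is.matrix(r) || ncol(r) != 2 || nrow(r) < 4) {
        msg <- c(msg, "each ring must be a closed 2-column matrix (>= 4 rows)")
        break
      }
      if (abs(polygonRingArea(r)) <= 0) {
        msg <- c(msg, "every ring must have nonzero area")
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' SpatialWeights: sparse contiguity-based spatial weights
#'
#' Neighbor structure for n spatial units with nonnegative weights, in the
#' adjacency-list form used by GAL files. Before standardization the queen
#' neighbor relation is symmetric; row standardization rescales each unit's
#' weights to sum to one. Gi* analysis forces \code{includeSelf = TRUE}
#' with binary weights.
#'
#' @slot ids character identifiers of the units.
#' @slot neighbors list of integer vectors; \code{neighbors[[i]]} are the
#'   indices of i's neighbors (sorted, no duplicates).
#' @slot weights list of numeric vectors parallel to \code{neighbors}.
#' @slot standardization \code{"binary"} or \code{"row"}.
#' @slot includeSelf logical; whether each unit neighbors itself.
#' @export
setClass("SpatialWeights",
  representation(
    ids = "character",
    neighbors = "list",
    weights = "list",
    standardization = "character",
    includeSelf = "logical"
  ),
  prototype(standardization = "binary", includeSelf = FALSE)
)

setValidity("SpatialWeights", function(object) {
  msg <- character()
  n <- length(object@ids)
  if (length(object@neighbors) != n || length(object@weights) != n)
    msg <- c(msg, "neighbors and weights must have one entry per unit")
  if (!object@standardization %in% c("binary", "row"))
    msg <- c(msg, "standardization must be 'binary' or 'row'")
  self <- isTRUE(object@includeSelf)
  for (i in seq_len(min(n, length(object@neighbors)))) {
    nb <- object@neighbors[[i]]
    wt <- object@weights[[i]]
    if (length(nb) != length(wt)) {
      msg <- c(msg, "each unit's neighbor and weight vectors must align")
      break
    }
    if (!self && any(nb == i)) {
      msg <- c(msg, "no unit may neighbor itself unless includeSelf")
      break
    }
    if (any(wt < 0)) {
      msg <- c(msg, "weights must be nonnegative")
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' CurveFit: one fitted member of the curve-regression family
#'
#' Result of fitting one of the eleven curve-estimation model forms to
#' (x = zonal SUM of DN, y = ODR in percent) pairs. Coefficients are on the
#' natural (back-transformed) scale of the model expression; slots unused
#' by a model are NA. \code{r2Transformed} is the coefficient of
#' determination on the fitting scale (ln y for the log-linearized models),
#' \code{r2Original} on the raw y scale.
#'
#' @slot model character, model name.
#' @slot coefficients named numeric, b0..b3 as used by the model.
#' @slot mu numeric, logistic offset parameter (NA for other models).
#' @slot r2Transformed numeric in [0, 1].
#' @slot r2Original numeric (can be negative for badly misspecified fits).
#' @slot nObs integer number of observations.
#' @export
setClass("CurveFit",
  representation(
    model = "character",
    coefficients = "numeric",
    mu = "numeric",
    r2Transformed = "numeric",
    r2Original = "numeric",
    nObs = "integer"
  )
)

setValidity("CurveFit", function(object) {
  msg <- character()
  if (!object@model %in% curveModelNames())
    msg <- c(msg, "unknown model name")
  if (!all(is.finite(object@coefficients)))
    msg <- c(msg, "coefficients must be finite")
  r2 <- object@r2Transformed
  if (!is.na(r2) && (r2 < -1e-12 || r2 > 1 + 1e-12))
    msg <- c(msg, "r2Transformed must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' GlobalMoran: global Moran's I with analytic and permutation inference
#'
#' @slot I observed global Moran's I.
#' @slot expectation theoretical expectation -1/(n-1).
#' @slot variance variance under the randomization assumption.
#' @slot z analytic z value (I - E) / sqrt(variance).
#' @slot pseudoP permutation pseudo p-value (NA when inference is
#'   analytic-only).
#' @slot nPermutations number of permutations used (0 for analytic).
#' @slot n number of spatial units.
#' @export
setClass("GlobalMoran",
  representation(
    I = "numeric",
    expectation = "numeric",
    variance = "numeric",
    z = "numeric",
    pseudoP = "numeric",
    nPermutations = "integer",
    n = "integer"
  )
)

setValidity("GlobalMoran", function(object) {
  msg <- character()
  if (object@variance <= 0) msg <- c(msg, "variance must be positive")
  zc <- (object@I - object@expectation) / sqrt(object@variance)
  if (abs(zc - object@z) > 1e-12 * max(1, abs(zc)))
    msg <- c(msg, "z must equal (I - expectation)/sqrt(variance)")
  p <- object@pseudoP
  if (!is.na(p) && (p <= 0 || p > 1))
    msg <- c(msg, "pseudoP must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})
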