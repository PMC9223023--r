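# Synthetic study inputs with known ground truth: square-lattice zone
# maps, Poisson DN rasters (clipped to the 0-63 DN range, mimicking sensor
# saturation), sigmoid-linked ODR tables with log-scale noise, and
# simultaneous-autoregressive (SAR) fields with a known spatial-dependence
# parameter. All generators are pure functions of (parameters, seed).

#' Generate a rows x cols lattice of square zones
#'
#' Zones tile the rectangle [0, cols*cellSize] x [0, rows*cellSize] in
#' row-major order (z001 is the north-west corner), so the queen adjacency
#' of the output matches the analytic lattice adjacency of
#' \code{\link{latticeQueenWeights}}.
#'
#' @param rows,cols lattice dimensions (>= 2).
#' @param cellSize zone side length in map units.
#' @param level zone level tag.
#' @return a \linkS4class{ZonePolygons}.
#' @export
generateLatticeZones <- function(rows, cols, cellSize = 1, level = "city") {
  stopifnot(rows >= 2, cols >= 2)
  ids <- sprintf("z%03d", seq_len(rows * cols))
  geoms <- vector("list", rows * cols)
  height <- rows * cellSize
  for (r in seq_len(rows)) for (c in seq_len(cols)) {
    i <- (r - 1L) * cols + c
    xmin <- (c - 1) * cellSize
    ymax <- height - (r - 1) * cellSize
    geoms[[i]] <- rectRing(xmin, ymax - cellSize, xmin + cellSize, ymax)
  }
  ZonePolygons(ids, geoms, level = level)
}

#' Generate a DN raster with per-zone brightness intensity
#'
#' Each square zone is subdivided into an m x m block of pixels
#' (\code{pixelsPerZone} = m^2) whose DN values are Poisson draws at the
#' zone's intensity, clipped to [0, 63] (saturation at the top of the DN
#' range). Zone mean DN converges to the clipped intensity as the pixel
#' count grows.
#'
#' @param zones a lattice \linkS4class{ZonePolygons} from
#'   \code{\link{generateLatticeZones}}.
#' @param intensity named numeric, zone_id -> mean DN in [0, 63].
#' @param pixelsPerZone pixels per zone; must be a perfect square.
#' @param seed integer seed.
#' @return a \linkS4class{LightRaster} aligned with the zone lattice.
#' @export
generateDnRaster <- function(zones, intensity, pixelsPerZone = 16L,
                             seed = 1L) {
  if (any(intensity < 0 | intensity > 63))
    stop("parameter error: intensities must lie in [0, 63]")
  m <- as.integer(round(sqrt(pixelsPerZone)))
  if (m * m != pixelsPerZone)
    stop("parameter error: pixelsPerZone must be a perfect square")
  ids <- zoneIds(zones)
  if (!all(ids %in% names(intensity)))
    stop("parameter error: intensity must name every zone")
  bbs <- lapply(zoneGeometry(zones), polygonBBox)
  allbb <- polygonBBox(unlist(zoneGeometry(zones), recursive = FALSE))
  side <- bbs[[1]]["xmax"] - bbs[[1]]["xmin"]
  cols <- as.integer(round((allbb["xmax"] - allbb["xmin"]) / side))
  rows <- as.integer(round((allbb["ymax"] - allbb["ymin"]) / side))
  px <- side / m
  nr <- rows * m; nc <- cols * m
  v <- matrix(0, nr, nc)
  set.seed(seed)
  for (i in seq_along(ids)) {
    bb <- bbs[[i]]
    c0 <- as.integer(round((bb["xmin"] - allbb["xmin"]) / side)) * m
    r0 <- as.integer(round((allbb["ymax"] - bb["ymax"]) / side)) * m
    vals <- pmin(63, rpois(m * m, intensity[[ids[i]]]))
    v[r0 + seq_len(m), c0 + seq_len(m)] <- matrix(vals, m, m)
  }
  gt <- c(allbb["xmin"], px, 0, allbb["ymax"], 0, -px)
  LightRaster(v, nodata = matrix(FALSE, nr, nc),
              geotransform = as.numeric(gt), crs = "cartesian")
}

#' Generate ODR values from the sigmoid brightness link
#'
#' odr_i = exp(b0 + b1 / x_i + e_i) with e_i ~ N(0, noiseSd^2): noise on
#' the log scale, so log-linearized OLS on the Sigmoid form is the
#' correctly specified estimator and parameter-recovery checks are sharp.
#'
#' @param sumDn positive SUM-of-DN values (one per zone).
#' @param b0,b1 sigmoid coefficients (percent scale; b1 < 0 gives an ODR
#'   rising with brightness toward the ceiling exp(b0)).
#' @param noiseSd log-scale noise standard deviation, >= 0.
#' @param seed integer seed.
#' @param ids optional zone identifiers.
#' @param year year label attached to the table.
#' @return data.frame: zone_id, year, sum_dn, odr.
#' @export
generateSigmoidOdr <- function(sumDn, b0, b1, noiseSd = 0, seed = 1L,
                               ids = NULL, year = 2020L) {
  stopifnot(all(sumDn > 0), noiseSd >= 0)
  if (is.null(ids)) ids <- sprintf("z%03d", seq_along(sumDn))
  set.seed(seed)
  eps <- rnorm(length(sumDn), 0, noiseSd)
  data.frame(zone_id = ids, year = year, sum_dn = sumDn,
             odr = exp(b0 + b1 / sumDn + eps), stringsAsFactors = FALSE)
}

#' Simulate a simultaneous-autoregressive (SAR) spatial field
#'
#' x = (I - rho W)^(-1) eps with W the row-standardized weight matrix and
#' eps standard normal, so rho = 0 reduces to an i.i.d. normal field and
#' rho near 1 produces strong positive spatial autocorrelation. Requires
#' |rho| < 1 (within the spectral bound of the row-standardized W).
#'
#' @param w a \linkS4class{SpatialWeights} (any standardization; row
#'   standardization is applied internally).
#' @param rho spatial-dependence parameter, |rho| < 1.
#' @param seed integer seed.
#' @return numeric field, one value per unit.
#' @export
generateSarField <- function(w, rho, seed = 1L) {
  if (abs(rho) >= 1) stop("parameter error: |rho| must be < 1")
  wr <- setWeightStandardization(w, "row")
  n <- length(wr@ids)
  tr <- weightsTriplets(wr)
  W <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$w, dims = c(n, n))
  A <- Matrix::Diagonal(n) - rho * W
  set.seed(seed)
  eps <- rnorm(n)
  as.vector(Matrix::solve(A, eps))
}
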