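# Zonal statistics workflow: reproject/resample the brightness raster onto
# an equal-area grid, assign cells to zones by their centers, and reduce to
# per-zone SUM and MEAN of DN with effective pixel counts.

cellCenters <- function(gt, nrows, ncols) {
  x <- gt[1] + (seq_len(ncols) - 0.5) * gt[2]
  y <- gt[4] + (seq_len(nrows) - 0.5) * gt[6]
  list(x = x, y = y)
}

# Keys cubic-convolution kernel, a = -0.5 (the resampling kernel used for
# continuous imagery; interpolates exactly at integer offsets).
keysKernel <- function(s, a = -0.5) {
  s <- abs(s)
  w <- numeric(length(s))
  i1 <- s <= 1
  w[i1] <- (a + 2) * s[i1]^3 - (a + 3) * s[i1]^2 + 1
  i2 <- s > 1 & s < 2
  w[i2] <- a * s[i2]^3 - 5 * a * s[i2]^2 + 8 * a * s[i2] - 4 * a
  w
}

#' Reproject and resample a brightness raster
#'
#' Builds a target grid in \code{targetCrs} at \code{cellSize} spacing and
#' samples the source raster at every target cell center (inverse
#' projection). \code{nearest} preserves integer DN; \code{bilinear} and
#' \code{cubic} (Keys kernel, a = -0.5) produce fractional values, with
#' cubic output clamped back to [0, 63] since the kernel can overshoot.
#' A target cell is nodata when its nearest source cell is nodata or it
#' falls outside the source extent; interpolation otherwise drops nodata
#' neighbors and renormalizes the kernel weights. When source and target
#' CRS coincide the target grid reuses the source origin, so an identity
#' resample with \code{nearest} is bit-exact.
#'
#' @param raster a \linkS4class{LightRaster}.
#' @param targetCrs CRS label of the output grid.
#' @param cellSize output cell size in target units (metres for Albers).
#' @param method \code{"nearest"}, \code{"bilinear"} or \code{"cubic"}.
#' @return a \linkS4class{LightRaster} on the target grid.
#' @export
reprojectResample <- function(raster, targetCrs = "albers_china",
                              cellSize, method = c("nearest", "bilinear",
                                                   "cubic")) {
  method <- match.arg(method)
  if (!crsIsKnown(targetCrs))
    stop("configuration error: unknown projection spec '", targetCrs, "'")
  v <- rasterValues(raster)
  if (length(v) == 0) stop("input error: empty raster")
  gt <- geoTransform(raster)
  nr <- nrow(v); nc <- ncol(v)
  srcCrs <- crsLabel(raster)
  same <- identical(srcCrs, targetCrs)

  if (same) {
    x0 <- gt[1]; y0 <- gt[4]
    ncT <- max(1L, as.integer(ceiling(nc * gt[2] / cellSize - 1e-9)))
    nrT <- max(1L, as.integer(ceiling(nr * (-gt[6]) / cellSize - 1e-9)))
  } else {
    # project a dense outline of the source extent to bound the target grid
    t <- seq(0, 1, length.out = 41)
    xs <- gt[1] + c(t * nc, rep(nc, 41), rev(t * nc), rep(0, 41)) * gt[2]
    ys <- gt[4] + c(rep(0, 41), t * nr, rep(nr, 41), rev(t * nr)) * gt[6]
    p <- projectPoints(xs, ys, srcCrs, targetCrs)
    x0 <- min(p$x); y0 <- max(p$y)
    ncT <- as.integer(ceiling((max(p$x) - x0) / cellSize))
    nrT <- as.integer(ceiling((y0 - min(p$y)) / cellSize))
  }
  gtT <- c(x0, cellSize, 0, y0, 0, -cellSize)

  cc <- cellCenters(gtT, nrT, ncT)
  X <- matrix(rep(cc$x, each = nrT), nrT, ncT)
  Y <- matrix(rep(cc$y, times = ncT), nrT, ncT)
  if (!same) {
    back <- projectPoints(as.vector(X), as.vector(Y), targetCrs, srcCrs)
    sx <- back$x; sy <- back$y
  } else {
    sx <- as.vector(X); sy <- as.vector(Y)
  }
  # fractional source indices: value rf = r at the center of source row r
  cf <- (sx - gt[1]) / gt[2] + 0.5
  rf <- (sy - gt[4]) / gt[6] + 0.5

  inExtent <- cf >= 0.5 - 1e-9 & cf <= nc + 0.5 + 1e-9 &
              rf >= 0.5 - 1e-9 & rf <= nr + 0.5 + 1e-9
  rn <- pmin(pmax(as.integer(round(rf)), 1L), nr)
  cn <- pmin(pmax(as.integer(round(cf)), 1L), nc)
  nearIdx <- cbind(rn, cn)
  nodataOut <- !inExtent | nodataMask(raster)[nearIdx]

  if (method == "nearest") {
    out <- v[nearIdx]
  } else {
    span <- if (method == "bilinear") 0:1 else -1:2
    base <- floor(rf); cbase <- floor(cf)
    num <- numeric(length(rf))
    den <- numeric(length(rf))
    valid <- !nodataMask(raster)
    for (dr in span) {
      ri <- pmin(pmax(as.integer(base + dr), 1L), nr)
      wr <- if (method == "bilinear") pmax(0, 1 - abs(rf - (base + dr)))
            else keysKernel(rf - (base + dr))
      for (dc in span) {
        ci <- pmin(pmax(as.integer(cbase + dc), 1L), nc)
        wc <- if (method == "bilinear") pmax(0, 1 - abs(cf - (cbase + dc)))
              else keysKernel(cf - (cbase + dc))
        idx <- cbind(ri, ci)
        ok <- valid[idx]
        w <- wr * wc * ok
        val <- v[idx]
        val[!ok] <- 0
        num <- num + w * val
        den <- den + w
      }
    }
    out <- ifelse(den != 0, num / den, NA_real_)
    nodataOut <- nodataOut | den == 0
    if (method == "cubic") out <- pmin(63, pmax(0, out))
  }
  out[nodataOut] <- NA_real_
  LightRaster(matrix(out, nrT, ncT), nodata = matrix(nodataOut, nrT, ncT),
              geotransform = gtT, crs = targetCrs,
              integerDN = method == "nearest" && isTRUE(raster@integerDN))
}

#' Assign raster cells to zones by cell-center containment
#'
#' A cell belongs to a zone iff its center lies inside (or on the boundary
#' of) the zone polygon. Nodata cells are never assigned. Cells whose
#' center falls on a shared boundary are claimed by the first zone in
#' ID-sorted order, so the assignment is deterministic and independent of
#' input feature ordering. A zone entirely outside the raster extent gets
#' an empty cell set with a warning.
#'
#' @param raster a \linkS4class{LightRaster}.
#' @param zones a \linkS4class{ZonePolygons} in the raster's coordinates.
#' @return named list: zone_id -> integer vector of cell indices into the
#'   value matrix (column-major), sorted increasing.
#' @export
maskExtract <- function(raster, zones) {
  v <- rasterValues(raster)
  nr <- nrow(v); nc <- ncol(v)
  cc <- cellCenters(geoTransform(raster), nr, nc)
  px <- rep(cc$x, each = nr)     # column-major order
  py <- rep(cc$y, times = nc)
  usable <- !as.vector(nodataMask(raster))
  assigned <- logical(nr * nc)
  ids <- zoneIds(zones)
  ord <- order(ids)
  out <- setNames(vector("list", length(ids)), ids)
  for (i in ord) {
    rings <- zoneGeometry(zones)[[i]]
    bb <- polygonBBox(rings)
    cand <- which(usable & !assigned &
                  px >= bb["xmin"] - .geomTol & px <= bb["xmax"] + .geomTol &
                  py >= bb["ymin"] - .geomTol & py <= bb["ymax"] + .geomTol)
    if (length(cand)) {
      hit <- pointsInPolygon(px[cand], py[cand], rings) > 0L
      cells <- cand[hit]
    } else cells <- integer(0)
    if (!length(cells))
      warning("zone '", ids[i], "' covers no usable raster cells")
    assigned[cells] <- TRUE
    out[[ids[i]]] <- sort(cells)
  }
  out
}

#' Per-zone SUM and MEAN of DN
#'
#' Reduces a cell assignment to zonal statistics: \code{sum_dn} is the
#' exact sum of DN over the zone's effective pixels (all assigned
#' non-nodata cells, zero-DN cells included), \code{mean_dn = sum_dn /
#' n_pixels}. Zones with no effective pixels are omitted with a message.
#'
#' @param raster a \linkS4class{LightRaster}.
#' @param cells named list from \code{\link{maskExtract}}.
#' @return data.frame with columns zone_id, sum_dn, mean_dn, n_pixels.
#' @export
zonalStats <- function(raster, cells) {
  v <- as.vector(rasterValues(raster))
  bad <- as.vector(nodataMask(raster))
  rows <- lapply(names(cells), function(id) {
    idx <- cells[[id]]
    if (!length(idx)) return(NULL)
    if (any(idx < 1 | idx > length(v)) || any(bad[idx]))
      stop("invalid or nodata cell referenced for zone '", id, "'")
    s <- sum(v[idx])
    data.frame(zone_id = id, sum_dn = s, mean_dn = s / length(idx),
               n_pixels = length(idx), stringsAsFactors = FALSE)
  })
  dropped <- names(cells)[vapply(rows, is.null, logical(1))]
  if (length(dropped))
    message("omitting zones with zero effective pixels: ",
            paste(dropped, collapse = ", "))
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(zone_id = character(0), sum_dn = numeric(0),
                      mean_dn = numeric(0), n_pixels = integer(0))
  out
}

#' Write zonal statistics as CSV
#'
#' @param stats data.frame from \code{\link{zonalStats}}.
#' @param path output CSV path.
#' @param level zone level recorded in the output.
#' @export
writeZonalStats <- function(stats, path, level = "city") {
  out <- data.frame(zone_id = stats$zone_id, level = level,
                    sum_dn = stats$sum_dn, mean_dn = stats$mean_dn,
                    n_pixels = stats$n_pixels)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
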