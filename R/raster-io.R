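#' Construct a LightRaster
#'
#' @param values numeric matrix of DN values (row 1 is the northernmost).
#' @param nodata logical matrix marking missing cells, or \code{NULL} to
#'   derive it from \code{nodataValue} / NA entries.
#' @param geotransform GDAL-style numeric(6) affine
#'   \code{c(x0, dx, 0, y0, 0, -dy)}.
#' @param crs CRS label (see \code{\link{crsIsKnown}}).
#' @param nodataValue scalar flagged as missing in \code{values}
#'   (DMSP/OLS convention 255); only used when \code{nodata} is NULL.
#' @param integerDN enforce the integer DN range invariant [0, 63].
#' @return a \linkS4class{LightRaster}.
#' @export
LightRaster <- function(values, nodata = NULL,
                        geotransform = c(0, 1, 0, nrow(values), 0, -1),
                        crs = "cartesian", nodataValue = 255,
                        integerDN = TRUE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(nodata)) {
    nodata <- is.na(values) | values == nodataValue
  }
  values[nodata] <- NA_real_
  new("LightRaster", values = values, nodata = nodata,
      geotransform = as.numeric(geotransform), crs = crs,
      integerDN = integerDN)
}

#' Read a single-band raster from an ESRI ASCII grid file
#'
#' Plain-text .asc rasters (ncols/nrows/xllcorner/yllcorner/cellsize header
#' plus a NODATA_value tag) are the text counterpart of the single-band
#' georeferenced rasters the zonal workflow consumes. The format carries no
#' CRS, so the label is supplied by the caller.
#'
#' @param path file path.
#' @param crs CRS label to attach.
#' @param integerDN enforce the integer DN invariant.
#' @return a \linkS4class{LightRaster}.
#' @export
readAsciiGrid <- function(path, crs = "cartesian", integerDN = TRUE) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("input error: malformed ASCII grid header in ", path)
  nodataValue <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else 255
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("input error: cell count does not match header in ", path)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  gt <- c(hdr$xllcorner, hdr$cellsize, 0,
          hdr$yllcorner + hdr$nrows * hdr$cellsize, 0, -hdr$cellsize)
  LightRaster(m, geotransform = gt, crs = crs, nodataValue = nodataValue,
              integerDN = integerDN)
}

#' Write a LightRaster as an ESRI ASCII grid
#'
#' Requires square cells (the .asc convention). Nodata cells are written as
#' the nodata value.
#'
#' @param raster a \linkS4class{LightRaster}.
#' @param path output file path.
#' @param nodataValue value to write for missing cells.
#' @export
writeAsciiGrid <- function(raster, path, nodataValue = 255) {
  gt <- geoTransform(raster)
  if (abs(gt[2] + gt[6]) > 1e-12 * gt[2])
    stop("ASCII grid output requires square cells")
  v <- rasterValues(raster)
  v[nodataMask(raster)] <- nodataValue
  hdr <- c(
    paste("ncols", ncol(v)),
    paste("nrows", nrow(v)),
    paste("xllcorner", format(gt[1], digits = 15)),
    paste("yllcorner", format(gt[4] + nrow(v) * gt[6], digits = 15)),
    paste("cellsize", format(gt[2], digits = 15)),
    paste("NODATA_value", nodataValue)
  )
  body <- apply(v, 1, function(row)
    paste(format(row, trim = TRUE, digits = 15), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Construct a ZonePolygons object
#'
#' @param zoneId character identifiers, unique within the level.
#' @param geometry list, one element per zone: either a single ring matrix
#'   or a list of ring matrices (multipolygon / holes). Rings are closed
#'   automatically when the first vertex is not repeated.
#' @param level \code{"province"} or \code{"city"}.
#' @return a \linkS4class{ZonePolygons}.
#' @export
ZonePolygons <- function(zoneId, geometry, level = "city") {
  if (is.matrix(geometry)) geometry <- list(geometry)
  geometry <- lapply(geometry, function(g) {
    if (is.matrix(g)) g <- list(g)
    lapply(g, function(r) {
      r <- as.matrix(r)
      if (any(r[1, ] != r[nrow(r), ])) r <- rbind(r, r[1, ])
      r
    })
  })
  new("ZonePolygons", zoneId = as.character(zoneId), geometry = geometry,
      level = level)
}

#' Read zone polygons from a GeoJSON file
#'
#' Accepts a FeatureCollection of Polygon / MultiPolygon features, taking
#' zone identifiers from a configurable property field.
#'
#' @param path GeoJSON file path.
#' @param idField property carrying the zone identifier.
#' @param level zone nesting level to record.
#' @return a \linkS4class{ZonePolygons}.
#' @export
readZonePolygons <- function(path, idField = "zone_id", level = "city") {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$features))
    stop("input error: not a GeoJSON FeatureCollection: ", path)
  ids <- character(0)
  geoms <- list()
  for (ft in gj$features) {
    id <- ft$properties[[idField]]
    if (is.null(id))
      stop("input error: feature lacks id field '", idField, "'")
    ringsOf <- function(poly) lapply(poly, function(ring)
      do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]]))))
    g <- ft$geometry
    rings <- switch(g$type,
      Polygon = ringsOf(g$coordinates),
      MultiPolygon = unlist(lapply(g$coordinates, ringsOf),
                            recursive = FALSE),
      stop("input error: unsupported geometry type ", g$type))
    ids <- c(ids, as.character(id))
    geoms[[length(geoms) + 1L]] <- rings
  }
  ZonePolygons(ids, geoms, level = level)
}

#' Write zone polygons to a GeoJSON file
#'
#' Each zone is emitted as one Polygon feature per ring set (rings beyond
#' the first are written as interior rings of the same Polygon).
#'
#' @param zones a \linkS4class{ZonePolygons}.
#' @param path output path.
#' @param idField property name for the zone identifier.
#' @export
writeZonePolygons <- function(zones, path, idField = "zone_id") {
  feats <- lapply(seq_along(zoneIds(zones)), function(i) {
    rings <- lapply(zoneGeometry(zones)[[i]], function(r)
      lapply(seq_len(nrow(r)), function(k) c(r[k, 1], r[k, 2])))
    list(type = "Feature",
         properties = setNames(
           list(zoneIds(zones)[i], zoneLevel(zones)), c(idField, "level")),
         geometry = list(type = "Polygon", coordinates = rings))
  })
  fc <- list(type = "FeatureCollection", features = feats)
  writeLines(jsonlite::toJSON(fc, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}
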