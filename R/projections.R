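# Coordinate systems are referenced by compact text labels stored in the
# LightRaster crs slot:
#   "cartesian"           planar coordinates, no projection defined
#   "wgs84"               geographic lon/lat in decimal degrees
#   "albers_china"        spherical Albers equal-area conic with the fixed
#                         China-extent parameters (central meridian 105 E,
#                         standard parallels 25 N and 47 N, origin 0 N)
#   "albers:lon0,lat1,lat2,lat0"  custom spherical Albers parameters
# Albers coordinates are metres on an authalic sphere of radius 6371007.2 m.

.albersR <- 6371007.2

#' Test whether a CRS label is understood
#'
#' @param label character CRS tag.
#' @return logical.
#' @export
crsIsKnown <- function(label) {
  label %in% c("cartesian", "wgs84", "albers_china") ||
    grepl("^albers:", label)
}

parseAlbers <- function(label) {
  if (label == "albers_china") {
    p <- c(105, 25, 47, 0)
  } else {
    p <- suppressWarnings(
      as.numeric(strsplit(sub("^albers:", "", label), ",")[[1]]))
    if (length(p) != 4 || anyNA(p))
      stop("configuration error: cannot parse Albers label '", label, "'")
  }
  d2r <- pi / 180
  lon0 <- p[1] * d2r; lat1 <- p[2] * d2r; lat2 <- p[3] * d2r
  lat0 <- p[4] * d2r
  n <- (sin(lat1) + sin(lat2)) / 2
  C <- cos(lat1)^2 + 2 * n * sin(lat1)
  rho0 <- .albersR * sqrt(C - 2 * n * sin(lat0)) / n
  list(lon0 = lon0, n = n, C = C, rho0 = rho0)
}

albersForward <- function(lon, lat, prm) {
  d2r <- pi / 180
  rho <- .albersR * sqrt(prm$C - 2 * prm$n * sin(lat * d2r)) / prm$n
  theta <- prm$n * (lon * d2r - prm$lon0)
  list(x = rho * sin(theta), y = prm$rho0 - rho * cos(theta))
}

albersInverse <- function(x, y, prm) {
  rho <- sqrt(x^2 + (prm$rho0 - y)^2)
  theta <- atan2(x, prm$rho0 - y)
  sinlat <- (prm$C - (rho * prm$n / .albersR)^2) / (2 * prm$n)
  sinlat <- pmin(1, pmax(-1, sinlat))
  r2d <- 180 / pi
  list(lon = (prm$lon0 + theta / prm$n) * r2d, lat = asin(sinlat) * r2d)
}

#' Project point coordinates between supported coordinate systems
#'
#' Transforms planar/geographic coordinates between the CRS labels the
#' package understands. Geographic coordinates are WGS84 lon/lat degrees;
#' Albers output is metres (spherical equal-area conic).
#'
#' @param x,y numeric coordinate vectors in \code{from}.
#' @param from,to CRS labels (see \code{\link{crsIsKnown}}).
#' @return list with numeric vectors \code{x} and \code{y} in \code{to}.
#' @export
projectPoints <- function(x, y, from, to) {
  if (!crsIsKnown(from) || !crsIsKnown(to))
    stop("configuration error: unknown projection spec '",
         if (!crsIsKnown(from)) from else to, "'")
  if (identical(from, to)) return(list(x = x, y = y))
  if (from == "cartesian" || to == "cartesian")
    stop("configuration error: 'cartesian' rasters carry no projection; ",
         "only identity transforms are defined for them")
  if (from == "wgs84") {
    prm <- parseAlbers(to)
    f <- albersForward(x, y, prm)
    return(list(x = f$x, y = f$y))
  }
  if (to == "wgs84") {
    prm <- parseAlbers(from)
    inv <- albersInverse(x, y, prm)
    return(list(x = inv$lon, y = inv$lat))
  }
  # albers -> albers via geographic
  inv <- albersInverse(x, y, parseAlbers(from))
  f <- albersForward(inv$lon, inv$lat, parseAlbers(to))
  list(x = f$x, y = f$y)
}
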