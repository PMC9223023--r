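# Queen-contiguity spatial weights: two zones are neighbors iff their
# polygons share at least one boundary point (a vertex or any stretch of
# edge). Weights are stored as adjacency lists (the GAL convention);
# standardization is recomputed from the neighbor structure on demand.

newWeights <- function(ids, neighbors, standardization = "binary",
                       includeSelf = FALSE) {
  neighbors <- lapply(neighbors, as.integer)
  w <- lapply(seq_along(neighbors), function(i) {
    k <- length(neighbors[[i]])
    if (standardization == "row" && k > 0) rep(1 / k, k) else rep(1, k)
  })
  new("SpatialWeights", ids = ids, neighbors = neighbors, weights = w,
      standardization = standardization, includeSelf = includeSelf)
}

#' Build queen-contiguity weights from zone polygons
#'
#' Units i and j are neighbors iff their polygons share at least one
#' boundary point. Islands (units with no neighbor) are retained with
#' empty neighbor sets and reported via a message; downstream statistics
#' flag or exclude them explicitly.
#'
#' @param zones a \linkS4class{ZonePolygons} with >= 2 zones.
#' @param standardization \code{"binary"} or \code{"row"}.
#' @param tol absolute coordinate tolerance for boundary sharing.
#' @return a \linkS4class{SpatialWeights}.
#' @export
buildQueenWeights <- function(zones, standardization = c("binary", "row"),
                              tol = .geomTol) {
  standardization <- match.arg(standardization)
  ids <- zoneIds(zones)
  n <- length(ids)
  if (n < 2) stop("need at least 2 zones to build contiguity weights")
  geom <- zoneGeometry(zones)
  bbs <- lapply(geom, polygonBBox)
  nb <- lapply(seq_len(n), function(i) integer(0))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (polygonsShareBoundary(geom[[i]], geom[[j]], tol)) {
      nb[[i]] <- c(nb[[i]], j)
      nb[[j]] <- c(nb[[j]], i)
    }
  }
  nb <- lapply(nb, sort)
  k <- vapply(nb, length, integer(1))
  if (any(k == 0))
    message("islands (no queen neighbors): ",
            paste(ids[k == 0], collapse = ", "))
  newWeights(ids, nb, standardization)
}

#' Analytic queen weights of a rows x cols lattice
#'
#' The closed-form queen adjacency of a regular grid (row-major unit
#' order): horizontal, vertical and diagonal grid neighbors.
#'
#' @param rows,cols lattice dimensions (>= 1).
#' @param standardization \code{"binary"} or \code{"row"}.
#' @param ids optional unit identifiers (default z001, z002, ...).
#' @return a \linkS4class{SpatialWeights}.
#' @export
latticeQueenWeights <- function(rows, cols,
                                standardization = c("binary", "row"),
                                ids = NULL) {
  standardization <- match.arg(standardization)
  n <- rows * cols
  if (is.null(ids)) ids <- sprintf("z%03d", seq_len(n))
  nb <- vector("list", n)
  for (r in seq_len(rows)) for (c in seq_len(cols)) {
    i <- (r - 1L) * cols + c
    adj <- integer(0)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr >= 1 && rr <= rows && cc >= 1 && cc <= cols)
        adj <- c(adj, (rr - 1L) * cols + cc)
    }
    nb[[i]] <- sort(adj)
  }
  newWeights(ids, nb, standardization)
}

#' Change the standardization of a weights object
#'
#' Recomputes weights from the neighbor structure: binary sets every
#' nonzero weight to 1; row standardization rescales each unit's weights
#' to sum to one (islands keep an empty set).
#'
#' @param w a \linkS4class{SpatialWeights}.
#' @param standardization \code{"binary"} or \code{"row"}.
#' @return a \linkS4class{SpatialWeights}.
#' @export
setWeightStandardization <- function(w, standardization = c("binary",
                                                            "row")) {
  standardization <- match.arg(standardization)
  newWeights(w@ids, w@neighbors, standardization, w@includeSelf)
}

#' Add self-neighbors (binary), as required by Gi*
#'
#' @param w a \linkS4class{SpatialWeights}.
#' @return binary weights with each unit included in its own neighborhood.
#' @export
includeSelfWeights <- function(w) {
  nb <- lapply(seq_along(w@neighbors), function(i)
    sort(unique(c(i, w@neighbors[[i]]))))
  newWeights(w@ids, nb, "binary", includeSelf = TRUE)
}

# triplet (i, j, w) view of the weights, for vectorized statistics
weightsTriplets <- function(w) {
  k <- cardinality(w)
  list(i = rep(seq_along(w@ids), k),
       j = unlist(w@neighbors, use.names = FALSE),
       w = unlist(w@weights, use.names = FALSE))
}

# spatial lag of z (NA for islands)
spatialLag <- function(w, z) {
  out <- vapply(seq_along(w@ids), function(i) {
    if (!length(w@neighbors[[i]])) return(NA_real_)
    sum(w@weights[[i]] * z[w@neighbors[[i]]])
  }, numeric(1))
  out
}

#' Write weights in the GAL adjacency-list convention
#'
#' Plain-text format: a header line with the unit count, then per unit a
#' line \code{id k} followed by a line listing the k neighbor ids.
#'
#' @param w a \linkS4class{SpatialWeights} (binary structure is written;
#'   standardization is not stored in GAL).
#' @param path output path.
#' @export
writeGal <- function(w, path) {
  lines <- as.character(length(w@ids))
  for (i in seq_along(w@ids)) {
    nbi <- w@neighbors[[i]]
    lines <- c(lines, paste(w@ids[i], length(nbi)),
               paste(w@ids[nbi], collapse = " "))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read weights from a GAL file
#'
#' @param path GAL file path.
#' @param standardization standardization applied after reading.
#' @return a \linkS4class{SpatialWeights}.
#' @export
readGal <- function(path, standardization = c("binary", "row")) {
  standardization <- match.arg(standardization)
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n <- as.integer(hdr[length(hdr)])  # tolerate "0 n shp id" headers
  if (length(hdr) >= 2) n <- as.integer(hdr[2])
  ids <- character(n)
  rawNb <- vector("list", n)
  ln <- 2L
  for (i in seq_len(n)) {
    head <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    ids[i] <- head[1]
    k <- as.integer(head[2])
    rawNb[[i]] <- if (k > 0)
      strsplit(trimws(lines[ln + 1L]), "\\s+")[[1]] else character(0)
    ln <- ln + 2L
  }
  nb <- lapply(rawNb, function(s) sort(match(s, ids)))
  newWeights(ids, nb, standardization)
}
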