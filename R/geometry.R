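# Planar geometry primitives for zone polygons: signed ring area, robust
# point-in-polygon (even-odd with explicit boundary detection), and segment
# intersection. Coordinates are plain planar (x, y); tolerances are absolute
# and suit the metre/degree scales used by the zone generators and readers.

.geomTol <- 1e-9

polygonRingArea <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}

# TRUE if point p lies on segment a-b (within tol of the segment).
pointOnSegment <- function(px, py, ax, ay, bx, by, tol = .geomTol) {
  cross <- (bx - ax) * (py - ay) - (by - ay) * (px - ax)
  len <- sqrt((bx - ax)^2 + (by - ay)^2)
  if (len == 0) return(abs(px - ax) < tol & abs(py - ay) < tol)
  dist <- abs(cross) / len
  dot <- (px - ax) * (bx - ax) + (py - ay) * (by - ay)
  dist < tol & dot > -tol * len & dot < len * len + tol * len
}

# Vectorized even-odd test of points against one closed ring.
# Returns integer: 0 outside, 1 inside, 2 on boundary.
pointsInRing <- function(px, py, ring, tol = .geomTol) {
  n <- nrow(ring) - 1L  # last vertex repeats the first
  res <- integer(length(px))
  inside <- logical(length(px))
  onb <- logical(length(px))
  for (k in seq_len(n)) {
    ax <- ring[k, 1]; ay <- ring[k, 2]
    bx <- ring[k + 1L, 1]; by <- ring[k + 1L, 2]
    onb <- onb | pointOnSegment(px, py, ax, ay, bx, by, tol)
    crosses <- ((ay > py) != (by > py)) &
      (px < (bx - ax) * (py - ay) / (by - ay) + ax)
    crosses[is.na(crosses)] <- FALSE
    inside <- xor(inside, crosses)
  }
  res[inside] <- 1L
  res[onb] <- 2L
  res
}

# Even-odd over all rings of a (multi)polygon; holes flip parity naturally.
# Returns 0 / 1 / 2 as above.
pointsInPolygon <- function(px, py, rings, tol = .geomTol) {
  parity <- integer(length(px))
  onb <- logical(length(px))
  for (ring in rings) {
    r <- pointsInRing(px, py, ring, tol)
    onb <- onb | (r == 2L)
    parity <- parity + as.integer(r == 1L)
  }
  out <- as.integer(parity %% 2L == 1L)
  out[onb] <- 2L
  out
}

polygonBBox <- function(rings) {
  xs <- unlist(lapply(rings, function(r) r[, 1]))
  ys <- unlist(lapply(rings, function(r) r[, 2]))
  c(xmin = min(xs), ymin = min(ys), xmax = max(xs), ymax = max(ys))
}

# Do segments a1-a2 and b1-b2 share at least one point (within tol)?
segmentsTouch <- function(a1, a2, b1, b2, tol = .geomTol) {
  d1 <- a2 - a1; d2 <- b2 - b1
  denom <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(denom) > tol) {
    t <- ((b1[1] - a1[1]) * d2[2] - (b1[2] - a1[2]) * d2[1]) / denom
    u <- ((b1[1] - a1[1]) * d1[2] - (b1[2] - a1[2]) * d1[1]) / denom
    return(t >= -tol && t <= 1 + tol && u >= -tol && u <= 1 + tol)
  }
  # parallel: touch iff an endpoint of one lies on the other
  pointOnSegment(a1[1], a1[2], b1[1], b1[2], b2[1], b2[2], tol) ||
    pointOnSegment(a2[1], a2[2], b1[1], b1[2], b2[1], b2[2], tol) ||
    pointOnSegment(b1[1], b1[2], a1[1], a1[2], a2[1], a2[2], tol) ||
    pointOnSegment(b2[1], b2[2], a1[1], a1[2], a2[1], a2[2], tol)
}

ringEdges <- function(ring) {
  n <- nrow(ring) - 1L
  lapply(seq_len(n), function(k) rbind(ring[k, ], ring[k + 1L, ]))
}

# Queen test: do two (multi)polygons share at least one boundary point?
polygonsShareBoundary <- function(ringsA, ringsB, tol = .geomTol) {
  ba <- polygonBBox(ringsA); bb <- polygonBBox(ringsB)
  if (ba["xmin"] > bb["xmax"] + tol || bb["xmin"] > ba["xmax"] + tol ||
      ba["ymin"] > bb["ymax"] + tol || bb["ymin"] > ba["ymax"] + tol)
    return(FALSE)
  edgesA <- unlist(lapply(ringsA, ringEdges), recursive = FALSE)
  edgesB <- unlist(lapply(ringsB, ringEdges), recursive = FALSE)
  for (ea in edgesA) {
    # cheap bbox cull per edge pair
    for (eb in edgesB) {
      if (max(ea[, 1]) < min(eb[, 1]) - tol ||
          max(eb[, 1]) < min(ea[, 1]) - tol ||
          max(ea[, 2]) < min(eb[, 2]) - tol ||
          max(eb[, 2]) < min(ea[, 2]) - tol) next
      if (segmentsTouch(ea[1, ], ea[2, ], eb[1, ], eb[2, ], tol))
        return(TRUE)
    }
  }
  FALSE
}

# closed rectangle ring (counter-clockwise)
rectRing <- function(xmin, ymin, xmax, ymax) {
  rbind(c(xmin, ymin), c(xmax, ymin), c(xmax, ymax), c(xmin, ymax),
        c(xmin, ymin))
}
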