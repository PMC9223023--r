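# Independent oracles, deliberately coded differently from the package
# internals: double-loop statistics straight from the defining formulas,
# a winding-number point-in-polygon test, a direct cubic-convolution
# resampler, and interval arithmetic for rectangle contiguity.

# Global Moran's I by explicit double loop over the dense weight matrix.
bruteGlobalMoran <- function(x, W) {
  n <- length(x)
  zbar <- mean(x)
  num <- 0
  for (i in 1:n) for (j in 1:n)
    num <- num + W[i, j] * (x[i] - zbar) * (x[j] - zbar)
  n * num / (sum(W) * sum((x - zbar)^2))
}

# Local Moran's I_i by explicit loop.
bruteLocalMoran <- function(x, W) {
  n <- length(x)
  zbar <- mean(x)
  denom <- sum((x - zbar)^2)
  sapply(1:n, function(i) {
    lag <- 0
    for (j in 1:n) lag <- lag + W[i, j] * (x[j] - zbar)
    n * (x[i] - zbar) * lag / denom
  })
}

# Getis-Ord Gi* term by term (binary weights with self included).
bruteGiStar <- function(x, Wself) {
  n <- length(x)
  xbar <- mean(x)
  S <- sqrt(sum(x^2) / n - xbar^2)
  sapply(1:n, function(i) {
    wsum <- sum(Wself[i, ])
    wsq <- sum(Wself[i, ]^2)
    num <- sum(Wself[i, ] * x) - xbar * wsum
    den <- S * sqrt((n * wsq - wsum^2) / (n - 1))
    if (den == 0) NA_real_ else num / den
  })
}

# Winding-number point-in-polygon (angle summation), boundary-inclusive.
windingInside <- function(px, py, ring, tol = 1e-9) {
  n <- nrow(ring) - 1
  total <- 0
  for (k in 1:n) {
    ax <- ring[k, 1] - px; ay <- ring[k, 2] - py
    bx <- ring[k + 1, 1] - px; by <- ring[k + 1, 2] - py
    cross <- ax * by - ay * bx
    dot <- ax * bx + ay * by
    la <- sqrt(ax^2 + ay^2); lb <- sqrt(bx^2 + by^2)
    if (la < tol || lb < tol) return(TRUE)              # on a vertex
    if (abs(cross) < tol * la * lb && dot <= 0) return(TRUE)  # on an edge
    total <- total + atan2(cross, dot)
  }
  abs(total) > pi
}

# Direct Keys cubic-convolution (a = -0.5) sampling at fractional source
# coordinates, replicate border, scalar loops throughout.
naiveKeys <- function(s, a = -0.5) {
  s <- abs(s)
  if (s <= 1) (a + 2) * s^3 - (a + 3) * s^2 + 1
  else if (s < 2) a * s^3 - 5 * a * s^2 + 8 * a * s - 4 * a
  else 0
}

naiveCubicSample <- function(v, rf, cf) {
  nr <- nrow(v); nc <- ncol(v)
  r0 <- floor(rf); c0 <- floor(cf)
  acc <- 0
  for (m in -1:2) for (k in -1:2) {
    ri <- min(max(r0 + m, 1), nr)
    ci <- min(max(c0 + k, 1), nc)
    acc <- acc + naiveKeys(rf - (r0 + m)) * naiveKeys(cf - (c0 + k)) *
      v[ri, ci]
  }
  acc
}

# Axis-aligned rectangles share a boundary point iff their closed
# intervals overlap on both axes (interval arithmetic, no geometry code).
rectsTouch <- function(a, b, tol = 1e-9) {
  min(a[3], b[3]) - max(a[1], b[1]) >= -tol &&
    min(a[4], b[4]) - max(a[2], b[2]) >= -tol
}

# n random non-overlapping rectangles: jittered cells of a coarse grid,
# some enlarged to touch their neighbors.
randomRectangles <- function(n, seed) {
  set.seed(seed)
  side <- ceiling(sqrt(n))
  cells <- sample(side * side, n)
  lapply(cells, function(cl) {
    r <- (cl - 1) %/% side
    c <- (cl - 1) %% side
    w <- runif(1, 0.4, 1)   # 1 reaches the shared grid line
    h <- runif(1, 0.4, 1)
    c(xmin = c, ymin = r, xmax = c + w, ymax = r + h)
  })
}

# random connected symmetric binary adjacency (spanning chain + extras)
randomAdjacency <- function(n, seed) {
  set.seed(seed)
  A <- matrix(0, n, n)
  ord <- sample(n)
  for (k in 2:n) A[ord[k - 1], ord[k]] <- A[ord[k], ord[k - 1]] <- 1
  extra <- max(1, round(n * 0.8))
  for (e in seq_len(extra)) {
    ij <- sample(n, 2)
    A[ij[1], ij[2]] <- A[ij[2], ij[1]] <- 1
  }
  A
}

weightsFromAdjacency <- function(A, standardization = "binary") {
  nb <- lapply(seq_len(nrow(A)), function(i) which(A[i, ] > 0))
  odrlight:::newWeights(sprintf("u%02d", seq_len(nrow(A))), nb,
                        standardization)
}
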