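# Global and local spatial autocorrelation of per-unit values under
# queen-contiguity weights. The global statistic is the cross-product
# Moran's I with expectation -1/(n-1); inference is either the analytic
# randomization variance (Cliff-Ord moments) or a conditional/full
# permutation distribution with pseudo p-values. Local statistics are the
# LISA decomposition with quadrant labels and Getis-Ord Gi* hot/cold-spot
# classification.

checkConnectivity <- function(w) {
  if (all(cardinality(w) == 0))
    stop("no-connectivity error: all units are islands")
}

moranNumerator <- function(tr, z) sum(tr$w * z[tr$i] * z[tr$j])

#' Bare global Moran's I statistic
#'
#' I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2 with z = x - mean(x)
#' and S0 the total weight. Exposed separately from
#' \code{\link{globalMoran}} so degenerate but well-defined cases (e.g.
#' n = 2 perfect dispersion, I = -1) can be evaluated without inference.
#'
#' @param x per-unit values.
#' @param w a \linkS4class{SpatialWeights}.
#' @return numeric I.
#' @export
moranI <- function(x, w) {
  n <- length(x)
  stopifnot(n == length(w@ids))
  checkConnectivity(w)
  if (var(x) == 0) stop("zero-variance error: x is constant")
  z <- x - mean(x)
  tr <- weightsTriplets(w)
  (n / sum(tr$w)) * moranNumerator(tr, z) / sum(z^2)
}

#' Global Moran's I with analytic or permutation inference
#'
#' Computes the global statistic and a z value. With
#' \code{inference = "randomization"} the variance is the analytic
#' Cliff-Ord randomization variance; with \code{"permutation"} the
#' variance is the empirical variance of I over \code{nPerm} random
#' relabelings and the two-sided pseudo p is
#' (1 + #permutations with |I - E| at least the observed) / (1 + nPerm).
#'
#' @param x per-unit values (length n >= 3, not constant).
#' @param w a \linkS4class{SpatialWeights}.
#' @param inference \code{"randomization"} or \code{"permutation"}.
#' @param nPerm number of permutations (permutation mode).
#' @param seed integer seed for the permutation draw.
#' @return a \linkS4class{GlobalMoran}.
#' @export
globalMoran <- function(x, w, inference = c("randomization",
                                            "permutation"),
                        nPerm = 999L, seed = 1L) {
  inference <- match.arg(inference)
  n <- length(x)
  if (n < 3) stop("sample-size error: need n >= 3 for inference")
  checkConnectivity(w)
  if (var(x) == 0) stop("zero-variance error: x is constant")
  z <- x - mean(x)
  tr <- weightsTriplets(w)
  S0 <- sum(tr$w)
  m2 <- sum(z^2)
  I <- (n / S0) * moranNumerator(tr, z) / m2
  EI <- -1 / (n - 1)

  if (inference == "randomization") {
    if (n < 4)
      stop("sample-size error: randomization variance needs n >= 4")
    # Cliff-Ord S1, S2 over the (possibly asymmetric) weight matrix
    key <- paste(tr$i, tr$j)
    tkey <- paste(tr$j, tr$i)
    wT <- tr$w[match(key, tkey)]
    wT[is.na(wT)] <- 0
    S1 <- sum((tr$w + wT)^2) / 2
    rs <- tapply(tr$w, tr$i, sum)
    cs <- tapply(tr$w, tr$j, sum)
    rowSum <- colSum <- numeric(n)
    rowSum[as.integer(names(rs))] <- rs
    colSum[as.integer(names(cs))] <- cs
    S2 <- sum((rowSum + colSum)^2)
    b2 <- n * sum(z^4) / m2^2
    VI <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
           b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
          ((n - 1) * (n - 2) * (n - 3) * S0^2) - EI^2
    zval <- (I - EI) / sqrt(VI)
    return(new("GlobalMoran", I = I, expectation = EI, variance = VI,
               z = zval, pseudoP = NA_real_, nPermutations = 0L,
               n = as.integer(n)))
  }

  set.seed(seed)
  Iperm <- vapply(seq_len(nPerm), function(k) {
    zp <- z[sample.int(n)]
    (n / S0) * moranNumerator(tr, zp) / m2
  }, numeric(1))
  VI <- var(Iperm)
  zval <- (I - EI) / sqrt(VI)
  p <- (1 + sum(abs(Iperm - EI) >= abs(I - EI))) / (1 + nPerm)
  new("GlobalMoran", I = I, expectation = EI, variance = VI, z = zval,
      pseudoP = p, nPermutations = as.integer(nPerm), n = as.integer(n))
}

#' Local Moran's I (LISA) with conditional permutation inference
#'
#' For each unit, I_i = n z_i lag_i / sum z^2 with lag_i the spatial lag
#' of the centered values. The z value uses E(I_i) = -1/(n-1) and the
#' empirical variance of I_i under conditional permutation (the other
#' n-1 values randomly reassigned to the neighbor slots). Quadrants are
#' labeled from the signs of the centered value and its lag (HH, LL, HL,
#' LH; zeros fall on the Low side). Islands have undefined lag: they are
#' flagged and excluded from inference rather than zero-filled.
#'
#' @param x per-unit values.
#' @param w a \linkS4class{SpatialWeights}.
#' @param nPerm conditional permutations per unit.
#' @param seed integer seed.
#' @return data.frame: unit_id, Ii, e_Ii, var_Ii, zi, quadrant, p
#'   (two-sided pseudo p), significant (ns/p05/p01), island.
#' @export
localMoran <- function(x, w, nPerm = 999L, seed = 1L) {
  n <- length(x)
  if (n < 3) stop("sample-size error: need n >= 3")
  checkConnectivity(w)
  if (var(x) == 0) stop("zero-variance error: x is constant")
  z <- x - mean(x)
  m2 <- sum(z^2)
  lag <- spatialLag(w, z)
  Ii <- n * z * lag / m2
  EI <- -1 / (n - 1)
  set.seed(seed)
  varI <- pI <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    nbi <- w@neighbors[[i]]
    ki <- length(nbi)
    if (!ki) next
    wt <- w@weights[[i]]
    pool <- z[-i]
    draws <- matrix(0, nPerm, ki)
    for (p in seq_len(nPerm))
      draws[p, ] <- pool[sample.int(n - 1L, ki)]
    lagPerm <- as.vector(draws %*% wt)
    Iperm <- n * z[i] * lagPerm / m2
    varI[i] <- var(Iperm)
    pI[i] <- (1 + sum(abs(Iperm - mean(Iperm)) >=
                        abs(Ii[i] - mean(Iperm)))) / (1 + nPerm)
  }
  zi <- (Ii - EI) / sqrt(varI)
  quadrant <- ifelse(z > 0 & lag > 0, "HH",
              ifelse(z <= 0 & lag <= 0, "LL",
              ifelse(z > 0, "HL", "LH")))
  island <- cardinality(w) == 0
  quadrant[island] <- NA_character_
  data.frame(unit_id = w@ids, Ii = Ii, e_Ii = EI, var_Ii = varI, zi = zi,
             quadrant = quadrant, p = pI,
             significant = classifySignificance(zi), island = island,
             stringsAsFactors = FALSE)
}

#' Getis-Ord Gi* hot/cold-spot statistic
#'
#' The self-inclusive local concentration z statistic: binary weights with
#' each unit in its own neighborhood (enforced regardless of the input
#' standardization), S the per-dataset standard deviation with divisor n.
#' Classification: |Gi*| >= 2.58 hot/cold at 99%, >= 1.96 at 95%,
#' otherwise not significant.
#'
#' @param x per-unit values (not constant).
#' @param w a \linkS4class{SpatialWeights}; its neighbor structure is used
#'   with binary self-inclusive weights.
#' @return data.frame: unit_id, gi_star, cls
#'   (cold_99/cold_95/ns/hot_95/hot_99).
#' @export
getisOrdGiStar <- function(x, w) {
  n <- length(x)
  if (n < 3) stop("sample-size error: need n >= 3")
  checkConnectivity(w)
  if (var(x) == 0) stop("zero-variance error: S = 0 for constant x")
  ws <- includeSelfWeights(w)
  xbar <- mean(x)
  S <- sqrt(sum(x^2) / n - xbar^2)
  gi <- vapply(seq_len(n), function(i) {
    nbi <- ws@neighbors[[i]]
    wsum <- length(nbi)           # binary weights
    wsq <- wsum                   # sum of squared binary weights
    num <- sum(x[nbi]) - xbar * wsum
    den <- S * sqrt((n * wsq - wsum^2) / (n - 1))
    if (den == 0) NA_real_ else num / den  # neighborhood spans all units
  }, numeric(1))
  cls <- ifelse(gi <= -2.58, "cold_99",
         ifelse(gi <= -1.96, "cold_95",
         ifelse(gi >= 2.58, "hot_99",
         ifelse(gi >= 1.96, "hot_95", "ns"))))
  data.frame(unit_id = w@ids, gi_star = gi, cls = cls,
             stringsAsFactors = FALSE)
}

#' Classify a z value against the 1.96 / 2.58 thresholds
#'
#' |z| < 1.96 is not significant; 1.96 <= |z| < 2.58 is significant at the
#' 0.05 level; |z| >= 2.58 at the 0.01 level (boundaries inclusive).
#'
#' @param z finite z value(s).
#' @return character vector: "ns", "p05" or "p01" (NA propagates).
#' @export
classifySignificance <- function(z) {
  ifelse(is.na(z), NA_character_,
         ifelse(abs(z) >= 2.58, "p01",
                ifelse(abs(z) >= 1.96, "p05", "ns")))
}

#' Write local statistics as CSV
#'
#' Fixed header \code{unit_id,stat,z,p,label} covering either LISA rows
#' (stat = Ii, label = quadrant:significance) or Gi* rows (stat = z =
#' gi_star, label = cls).
#'
#' @param df output of \code{\link{localMoran}} or
#'   \code{\link{getisOrdGiStar}}.
#' @param path output CSV path.
#' @export
writeLocalStats <- function(df, path) {
  out <- if ("gi_star" %in% names(df)) {
    data.frame(unit_id = df$unit_id, stat = df$gi_star, z = df$gi_star,
               p = NA_real_, label = df$cls)
  } else {
    data.frame(unit_id = df$unit_id, stat = df$Ii, z = df$zi, p = df$p,
               label = paste(df$quadrant, df$significant, sep = ":"))
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
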