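# Curve-estimation model family for predicting the old-age dependency
# ratio (ODR, in percent) from the zonal SUM of DN. The eleven functional
# forms and their fitting conventions follow SPSS curve estimation: the
# intrinsically exponential forms are fitted by OLS on ln(y) against the
# model's x-transform and the coefficients back-transformed, so R^2 on the
# fitting (transformed) scale is the model-selection metric; the
# original-scale R^2 is reported alongside for transparency.

.curveRegistry <- list(
  Linear      = list(nParams = 2L, scale = "original"),
  Logarithmic = list(nParams = 2L, scale = "original"),
  Inverse     = list(nParams = 2L, scale = "original"),
  Quadratic   = list(nParams = 3L, scale = "original"),
  Cubic       = list(nParams = 4L, scale = "original"),
  Compound    = list(nParams = 2L, scale = "log-linearized"),
  Power       = list(nParams = 2L, scale = "log-linearized"),
  Sigmoid     = list(nParams = 2L, scale = "log-linearized"),
  Growth      = list(nParams = 2L, scale = "log-linearized"),
  Exponential = list(nParams = 2L, scale = "log-linearized"),
  Logistic    = list(nParams = 2L, scale = "log-linearized")
)

#' Names of the curve-regression model family
#'
#' @return character vector of the eleven model names, in the fixed order
#'   used for tie-breaking.
#' @export
curveModelNames <- function() names(.curveRegistry)

#' Describe one member of the curve model family
#'
#' @param name model name (see \code{\link{curveModelNames}}).
#' @return list with \code{name}, \code{nParams} and \code{fittingScale}.
#' @export
curveModelSpec <- function(name) {
  name <- match.arg(name, curveModelNames())
  m <- .curveRegistry[[name]]
  list(name = name, nParams = m$nParams, fittingScale = m$scale)
}

#' Old-age dependency ratio
#'
#' ODR = 100 x (population aged 65+) / (population aged 15-64), the
#' percentage of old-age dependents per hundred working-age people.
#'
#' @param p65plus old-age population count(s), >= 0.
#' @param p15to64 working-age population count(s), > 0.
#' @return ODR in percent (vectorized).
#' @export
computeOdr <- function(p65plus, p15to64) {
  if (any(p15to64 <= 0))
    stop("domain error: working-age population must be strictly positive")
  if (any(p65plus < 0))
    stop("domain error: old-age population must be nonnegative")
  100 * p65plus / p15to64
}

curveDesign <- function(name, x, y, mu) {
  switch(name,
    Linear      = list(X = cbind(1, x), r = y),
    Logarithmic = list(X = cbind(1, log(x)), r = y),
    Inverse     = list(X = cbind(1, 1 / x), r = y),
    Quadratic   = list(X = cbind(1, x, x^2), r = y),
    Cubic       = list(X = cbind(1, x, x^2, x^3), r = y),
    Compound    = list(X = cbind(1, x), r = log(y)),
    Power       = list(X = cbind(1, log(x)), r = log(y)),
    Sigmoid     = list(X = cbind(1, 1 / x), r = log(y)),
    Growth      = list(X = cbind(1, x), r = log(y)),
    Exponential = list(X = cbind(1, x), r = log(y)),
    Logistic    = list(X = cbind(1, x), r = log(1 / y - 1 / mu))
  )
}

curveBackTransform <- function(name, a) {
  switch(name,
    Linear      = c(b0 = a[1], b1 = a[2]),
    Logarithmic = c(b0 = a[1], b1 = a[2]),
    Inverse     = c(b0 = a[1], b1 = a[2]),
    Quadratic   = c(b0 = a[1], b1 = a[2], b2 = a[3]),
    Cubic       = c(b0 = a[1], b1 = a[2], b2 = a[3], b3 = a[4]),
    Compound    = c(b0 = exp(a[1]), b1 = exp(a[2])),
    Power       = c(b0 = exp(a[1]), b1 = a[2]),
    Sigmoid     = c(b0 = a[1], b1 = a[2]),
    Growth      = c(b0 = a[1], b1 = a[2]),
    Exponential = c(b0 = exp(a[1]), b1 = a[2]),
    Logistic    = c(b0 = exp(a[1]), b1 = exp(a[2]))
  )
}

checkCurveDomain <- function(name, x, y, mu) {
  if (name %in% c("Logarithmic", "Power") && any(x <= 0))
    stop("domain error: ", name, " requires x > 0; offending points: ",
         paste(which(x <= 0), collapse = ", "))
  if (name %in% c("Inverse", "Sigmoid") && any(x == 0))
    stop("domain error: ", name, " requires x != 0; offending points: ",
         paste(which(x == 0), collapse = ", "))
  if (name %in% c("Compound", "Power", "Sigmoid", "Growth", "Exponential",
                  "Logistic") && any(y <= 0))
    stop("domain error: ", name, " requires y > 0; offending points: ",
         paste(which(y <= 0), collapse = ", "))
  if (name == "Logistic" && any(1 / y - 1 / mu <= 0))
    stop("domain error: Logistic requires y < mu; offending points: ",
         paste(which(1 / y - 1 / mu <= 0), collapse = ", "))
}

#' Fit one curve-regression model to (SUM of DN, ODR) pairs
#'
#' Polynomial-type forms (Linear, Logarithmic, Inverse, Quadratic, Cubic)
#' are fitted by OLS on the transformed x; the exponential-type forms
#' (Compound, Power, Sigmoid, Growth, Exponential) by OLS on ln(y), with
#' coefficients back-transformed to the model expression. The Logistic
#' form is fitted by OLS on ln(1/y - 1/mu); by the package's curve
#' estimation convention \code{mu} defaults to the mean of x
#' (\code{logisticMuMode = "mean_x"}), or a fixed upper bound can be
#' supplied (\code{"fixed_bound"} with \code{mu}).
#'
#' @param x predictor values (zonal SUM of DN).
#' @param y response values (ODR in percent).
#' @param model model name from \code{\link{curveModelNames}}.
#' @param logisticMuMode how the Logistic mu parameter is chosen.
#' @param mu fixed bound for \code{logisticMuMode = "fixed_bound"}.
#' @return a \linkS4class{CurveFit}.
#' @export
fitCurveModel <- function(x, y, model,
                          logisticMuMode = c("mean_x", "fixed_bound"),
                          mu = NULL) {
  model <- match.arg(model, curveModelNames())
  logisticMuMode <- match.arg(logisticMuMode)
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  np <- .curveRegistry[[model]]$nParams
  if (length(x) < np)
    stop("fit error: ", model, " needs at least ", np, " points")
  muUse <- NA_real_
  if (model == "Logistic") {
    muUse <- if (logisticMuMode == "mean_x") mean(x) else {
      if (is.null(mu)) stop("fixed_bound mode requires mu")
      mu
    }
  }
  checkCurveDomain(model, x, y, muUse)
  d <- curveDesign(model, x, y, muUse)
  qrX <- qr(d$X)
  if (qrX$rank < ncol(d$X))
    stop("fit error: rank-deficient design for ", model)
  a <- qr.coef(qrX, d$r)
  fitted <- as.vector(d$X %*% a)
  ssTot <- sum((d$r - mean(d$r))^2)
  r2t <- if (ssTot > 0) 1 - sum((d$r - fitted)^2) / ssTot else NA_real_
  r2t <- min(1, max(0, r2t))
  cf <- curveBackTransform(model, unname(a))
  fit <- new("CurveFit", model = model, coefficients = cf, mu = muUse,
             r2Transformed = r2t, r2Original = NA_real_,
             nObs = length(x))
  yhat <- predictCurve(fit, x)
  ssT0 <- sum((y - mean(y))^2)
  fit@r2Original <- if (ssT0 > 0) 1 - sum((y - yhat)^2) / ssT0 else NA_real_
  fit
}

#' Evaluate a fitted curve model
#'
#' @param fit a \linkS4class{CurveFit}.
#' @param x predictor values.
#' @return predicted ODR (percent).
#' @export
predictCurve <- function(fit, x) {
  b <- fit@coefficients
  switch(fit@model,
    Linear      = b["b0"] + b["b1"] * x,
    Logarithmic = b["b0"] + b["b1"] * log(x),
    Inverse     = b["b0"] + b["b1"] / x,
    Quadratic   = b["b0"] + b["b1"] * x + b["b2"] * x^2,
    Cubic       = b["b0"] + b["b1"] * x + b["b2"] * x^2 + b["b3"] * x^3,
    Compound    = b["b0"] * b["b1"]^x,
    Power       = b["b0"] * x^b["b1"],
    Sigmoid     = exp(b["b0"] + b["b1"] / x),
    Growth      = exp(b["b0"] + b["b1"] * x),
    Exponential = b["b0"] * exp(b["b1"] * x),
    Logistic    = 1 / (1 / fit@mu + b["b0"] * b["b1"]^x)
  ) |> unname()
}

#' Predict municipal ODR from a fitted Sigmoid model
#'
#' The Sigmoid form y = exp(b0 + b1/x) rises from exp(b0 + b1/x -> 0) to
#' the finite ceiling exp(b0) as brightness grows; with b1 < 0 it is
#' strictly increasing in x.
#'
#' @param fit a Sigmoid \linkS4class{CurveFit}.
#' @param x SUM of DN values, > 0.
#' @return predicted ODR in percent.
#' @export
predictSigmoid <- function(fit, x) {
  if (fit@model != "Sigmoid") stop("fit is not a Sigmoid model")
  if (any(x <= 0)) stop("domain error: Sigmoid prediction requires x > 0")
  b <- fit@coefficients
  unname(exp(b["b0"] + b["b1"] / x))
}

#' Solve the Sigmoid model exactly from two (x, y) points
#'
#' Two points determine the two-parameter form y = exp(b0 + b1/x):
#' b1 = (ln y1 - ln y2) / (1/x1 - 1/x2) and b0 = ln y1 - b1/x1. Used to
#' reconstruct a published prediction curve from printed (SUM of DN, ODR)
#' rows when the fitted coefficients themselves are not reported.
#'
#' @param p1,p2 numeric length-2 vectors (x, y), x > 0, y > 0, x1 != x2.
#' @return a Sigmoid \linkS4class{CurveFit} (R^2 = 1 by construction).
#' @export
recoverSigmoidFromTwoPoints <- function(p1, p2) {
  x1 <- p1[1]; y1 <- p1[2]; x2 <- p2[1]; y2 <- p2[2]
  if (x1 <= 0 || x2 <= 0 || y1 <= 0 || y2 <= 0)
    stop("domain error: both points need x > 0 and y > 0")
  if (x1 == x2)
    stop("degenerate input: coincident x values cannot determine the curve")
  b1 <- (log(y1) - log(y2)) / (1 / x1 - 1 / x2)
  b0 <- log(y1) - b1 / x1
  new("CurveFit", model = "Sigmoid",
      coefficients = c(b0 = unname(b0), b1 = unname(b1)), mu = NA_real_,
      r2Transformed = 1, r2Original = 1, nObs = 2L)
}

#' Fit all models across years and rank them by mean R-squared
#'
#' Fits the full model family to each year's (x, y) points and tabulates
#' the fitting-scale R-squared per (model, year) plus the per-model mean.
#' A model that fails on a year (domain or rank error) records NA for that
#' cell, is excluded from that model's mean, and triggers a warning. The
#' best model maximizes the mean; ties break toward fewer parameters, then
#' the fixed model-name order.
#'
#' @param series named list, one element per year label, each a data.frame
#'   or list with components \code{x} and \code{y}.
#' @param models model names to include (default: all eleven).
#' @return list with \code{table} (data.frame of R-squared values, models
#'   in rows, year columns plus \code{Mean}) and \code{best} (model name).
#' @export
compareModels <- function(series, models = curveModelNames()) {
  years <- names(series)
  tab <- matrix(NA_real_, length(models), length(years),
                dimnames = list(models, years))
  for (yr in years) {
    d <- series[[yr]]
    for (m in models) {
      r2 <- tryCatch(fitCurveModel(d$x, d$y, m)@r2Transformed,
                     error = function(e) {
                       warning("model ", m, " failed for ", yr, ": ",
                               conditionMessage(e), call. = FALSE)
                       NA_real_
                     })
      tab[m, yr] <- r2
    }
  }
  meanR2 <- rowMeans(tab, na.rm = TRUE)
  meanR2[is.nan(meanR2)] <- NA_real_
  npar <- vapply(models, function(m) .curveRegistry[[m]]$nParams,
                 integer(1))
  ord <- order(-meanR2, npar, match(models, curveModelNames()),
               na.last = TRUE)
  best <- models[ord[1]]
  out <- data.frame(tab, Mean = meanR2, check.names = FALSE)
  list(table = out, best = best)
}

#' Filter for large and medium-sized cities
#'
#' Keeps records whose ODR, rounded to two decimals, meets \code{odrMin}
#' and whose SUM of DN meets \code{sumMin}; the result is sorted by ODR
#' descending. The two-decimal rounding makes the published style of
#' cutoff (a value itself printed to 2 dp) reproducible at the boundary.
#'
#' @param records data.frame with columns \code{zone_id}, \code{sum_dn},
#'   \code{odr}.
#' @param odrMin minimum ODR in percent (after 2-dp rounding).
#' @param sumMin minimum SUM of DN.
#' @return filtered, sorted data.frame.
#' @export
filterLargeCities <- function(records, odrMin = 13.71, sumMin = 115762) {
  if (!nrow(records)) return(records)
  keep <- round(records$odr, 2) >= odrMin & records$sum_dn >= sumMin
  out <- records[keep, , drop = FALSE]
  out[order(-out$odr), , drop = FALSE]
}

#' Bundled municipal prediction table for 65 large and medium-sized cities
#'
#' The published municipal SUM of DN and predicted ODR values for the 65
#' Chinese large and medium-sized cities that satisfy the standard filter
#' (ODR >= 13.71, SUM of DN >= 115,762). Useful as a worked-example input
#' and for validating a reconstructed Sigmoid curve by back-prediction.
#'
#' @return data.frame with columns \code{zone_id} (city name),
#'   \code{sum_dn}, \code{odr}.
#' @export
cityPredictionTable <- function() {
  read.csv(system.file("extdata", "china_city_odr_predictions.csv",
                       package = "odrlight"), stringsAsFactors = FALSE)
}

#' Write curve-fit results as CSV
#'
#' One row per (model, year): coefficients (unused ones empty) and both
#' R-squared values, header
#' \code{model,year,b0,b1,b2,b3,r2_transformed,r2_original}.
#'
#' @param fits named list of lists: year -> model -> CurveFit.
#' @param path output CSV path.
#' @export
writeFitResults <- function(fits, path) {
  rows <- list()
  for (yr in names(fits)) for (m in names(fits[[yr]])) {
    f <- fits[[yr]][[m]]
    cf <- f@coefficients
    g <- function(k) if (k %in% names(cf)) cf[[k]] else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      model = m, year = yr, b0 = g("b0"), b1 = g("b1"), b2 = g("b2"),
      b3 = g("b3"), r2_transformed = f@r2Transformed,
      r2_original = f@r2Original)
  }
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
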