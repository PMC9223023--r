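# The ODR definition and the eleven-member curve-regression family.

test_that("the ODR definition handles hand cases and inverts the Suzhou
           census figure", {
  expect_equal(computeOdr(0, 1000), 0)
  expect_equal(computeOdr(10, 100), 10)
  expect_error(computeOdr(5, 0), "domain error")
  # census old-age count with the working-age population reconstructed by
  # inverting the definition from the published percentage
  p65 <- 1585701
  p15to64 <- round(100 * p65 / 16.806)
  expect_equal(computeOdr(p65, p15to64), 16.806, tolerance = 1e-3)
})

test_that("exact data are recovered exactly by every model in the
           family", {
  set.seed(21)
  x <- sort(runif(20, 1, 50))
  truth <- list(
    Linear = function(x) 2 + 3 * x,
    Logarithmic = function(x) 1 + 2 * log(x),
    Inverse = function(x) 4 + 9 / x,
    Quadratic = function(x) 1 + 0.5 * x + 0.02 * x^2,
    Cubic = function(x) 2 + 0.3 * x - 0.01 * x^2 + 1e-4 * x^3,
    Compound = function(x) 3 * 1.04^x,
    Power = function(x) 2.5 * x^0.7,
    Sigmoid = function(x) exp(3.019 - 20 / x),
    Growth = function(x) exp(0.5 + 0.05 * x),
    Exponential = function(x) 1.5 * exp(0.06 * x)
  )
  for (m in names(truth)) {
    fit <- fitCurveModel(x, truth[[m]](x), m)
    expect_equal(fit@r2Transformed, 1, tolerance = 1e-9, info = m)
    expect_equal(predictCurve(fit, x), truth[[m]](x), tolerance = 1e-6,
                 info = m)
  }
  # linear coefficients recovered exactly
  fl <- fitCurveModel(x, 2 + 3 * x, "Linear")
  expect_equal(unname(fl@coefficients), c(2, 3), tolerance = 1e-9)
  # sigmoid coefficients recovered to 1e-9
  fs <- fitCurveModel(x * 1e4, exp(3.019 - 46452 / (x * 1e4)), "Sigmoid")
  expect_equal(unname(fs@coefficients), c(3.019, -46452),
               tolerance = 1e-9)
})

test_that("the logistic form follows the mean-of-x convention and the
           fixed-bound switch", {
  set.seed(3)
  x <- sort(runif(15, 10, 100))
  y <- runif(15, 1, 5)
  f1 <- fitCurveModel(x, y, "Logistic")
  expect_equal(f1@mu, mean(x))
  f2 <- fitCurveModel(x, y, "Logistic", logisticMuMode = "fixed_bound",
                      mu = 50)
  expect_equal(f2@mu, 50)
  # exact recovery when data follow the form
  yq <- 1 / (1 / mean(x) + 0.2 * 0.97^x)
  fq <- fitCurveModel(x, yq, "Logistic")
  expect_equal(unname(fq@coefficients), c(0.2, 0.97), tolerance = 1e-9)
})

test_that("domain violations and degenerate designs raise errors", {
  x <- 1:10
  expect_error(fitCurveModel(x, c(-1, 2:10), "Sigmoid"), "domain error")
  expect_error(fitCurveModel(c(0, 2:10), 1:10 + 0.5, "Power"),
               "domain error")
  expect_error(fitCurveModel(rep(2, 5), 1:5, "Linear"), "rank-deficient")
  expect_error(fitCurveModel(1:2, 1:2, "Cubic"), "at least 4")
})

test_that("Growth, Compound and Exponential share one fitting scale and
           identical R2", {
  set.seed(17)
  x <- runif(31, 1e4, 4e5)
  y <- exp(runif(31, 1, 3))
  r2 <- sapply(c("Growth", "Compound", "Exponential"),
               function(m) fitCurveModel(x, y, m)@r2Transformed)
  expect_lt(max(r2) - min(r2), 1e-12)
  # and their predictions coincide, being reparameterizations
  fg <- fitCurveModel(x, y, "Growth")
  fc <- fitCurveModel(x, y, "Compound")
  expect_equal(predictCurve(fg, x), predictCurve(fc, x),
               tolerance = 1e-9)
})

test_that("model comparison ranks, ties and repeats behave as
           documented", {
  x <- seq(1, 30)
  lin <- list(x = x, y = 2 + 0.5 * x)
  cmp <- suppressWarnings(compareModels(list(y1 = lin)))
  expect_equal(cmp$table["Linear", "Mean"], 1, tolerance = 1e-12)
  expect_equal(cmp$best, "Linear")  # 2 params beat exact Quadratic/Cubic

  set.seed(33)
  xs <- exp(runif(31, log(3e4), log(4e5)))
  ys <- generateSigmoidOdr(xs, 3.019, -46452, noiseSd = 0.05,
                           seed = 8)$odr
  two <- list(a = list(x = xs, y = ys), b = list(x = xs, y = ys))
  tab <- suppressWarnings(compareModels(two))$table
  expect_identical(tab[["a"]], tab[["b"]])

  series <- lapply(1:10, function(k) {
    xk <- exp(runif(31, log(3e4), log(4e5)))
    list(x = xk, y = generateSigmoidOdr(xk, 3.019, -46452, 0.05,
                                        seed = 100 + k)$odr)
  })
  names(series) <- paste0("yr", 1:10)
  expect_equal(suppressWarnings(compareModels(series))$best, "Sigmoid")
})

test_that("sigmoid fits beat the linear model on sigmoid-generated data
           in at least 95% of replicates", {
  wins <- 0
  for (r in 1:200) {
    set.seed(2 * r)         # x and noise on separate streams
    x <- exp(runif(31, log(3e4), log(4e5)))
    y <- generateSigmoidOdr(x, 3.019, -46452, 0.05, seed = 2 * r + 1)$odr
    wins <- wins + (fitCurveModel(x, y, "Sigmoid")@r2Transformed >
                      fitCurveModel(x, y, "Linear")@r2Transformed)
  }
  expect_gte(wins / 200, 0.95)
})

test_that("sigmoid prediction is monotone with a finite ceiling and
           reproduces the published city rows", {
  flat <- recoverSigmoidFromTwoPoints(c(1, exp(2)), c(2, exp(2)))
  expect_equal(predictSigmoid(flat, c(1, 10, 1000)), rep(exp(2), 3))

  fit <- recoverSigmoidFromTwoPoints(c(349408, 17.923), c(265159, 17.182))
  expect_lt(abs(predictSigmoid(fit, 373261) - 18.076), 0.01)
  expect_lt(abs(predictSigmoid(fit, 115762) - 13.706), 0.01)
  expect_error(predictSigmoid(fit, -5), "domain error")
  # b1 < 0: strictly increasing in x, ceiling exp(b0)
  b <- fit@coefficients
  expect_lt(b[["b1"]], 0)
  xs <- seq(1e5, 4e5, length.out = 50)
  expect_true(all(diff(predictSigmoid(fit, xs)) > 0))
  expect_lt(max(predictSigmoid(fit, xs)), exp(b[["b0"]]))
})

test_that("the two-point solver is exact and rejects degenerate input", {
  expect_error(recoverSigmoidFromTwoPoints(c(10, 1), c(10, 2)),
               "degenerate")
  set.seed(6)
  for (k in 1:20) {
    b0 <- runif(1, 1, 4); b1 <- runif(1, -6e4, -1e3)
    x <- sort(runif(2, 5e4, 5e5))
    fit <- recoverSigmoidFromTwoPoints(c(x[1], exp(b0 + b1 / x[1])),
                                       c(x[2], exp(b0 + b1 / x[2])))
    expect_equal(unname(fit@coefficients), c(b0, b1),
                 tolerance = 1e-9)
    expect_equal(predictSigmoid(fit, x), exp(b0 + b1 / x),
                 tolerance = 1e-12)
  }
})

test_that("the large-city filter applies rounded thresholds and sorts by
           ODR", {
  empty <- data.frame(zone_id = character(0), sum_dn = numeric(0),
                      odr = numeric(0))
  expect_equal(nrow(filterLargeCities(empty)), 0)
  rec <- data.frame(zone_id = c("a", "b", "c", "d"),
                    sum_dn = c(115761, 115762, 2e5, 2e5),
                    odr = c(20, 13.7049, 13.706, 15))
  out <- filterLargeCities(rec)
  # a: brightness below cutoff; b: 13.7049 rounds to 13.70 < 13.71
  expect_identical(out$zone_id, c("d", "c"))
  expect_true(all(diff(out$odr) <= 0))
})
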