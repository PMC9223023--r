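# Raster resampling, zone extraction and zonal SUM/MEAN of DN.

test_that("constant fields are invariant under resampling and identity
           nearest resampling is bit-exact", {
  v <- matrix(10, 8, 8)
  r <- LightRaster(v, geotransform = c(0, 1, 0, 8, 0, -1))
  for (m in c("nearest", "bilinear", "cubic")) {
    out <- reprojectResample(r, "cartesian", cellSize = 2, method = m)
    expect_true(all(rasterValues(out) == 10), info = m)
  }
  set.seed(11)
  v2 <- matrix(sample(0:63, 16, replace = TRUE), 4, 4)
  r2 <- LightRaster(v2, geotransform = c(0, 1, 0, 4, 0, -1))
  out2 <- reprojectResample(r2, "cartesian", cellSize = 1,
                            method = "nearest")
  expect_identical(rasterValues(out2), rasterValues(r2))
  expect_identical(geoTransform(out2), geoTransform(r2))
})

test_that("cubic resampling matches a direct Keys convolution oracle", {
  ramp <- outer(1:8, 1:8, function(i, j) (3 * i + 2 * j) %% 60)
  r <- LightRaster(ramp, geotransform = c(0, 1, 0, 8, 0, -1))
  out <- reprojectResample(r, "cartesian", cellSize = 2, method = "cubic")
  vo <- rasterValues(out)
  for (tr in 1:4) for (tc in 1:4) {
    # target center in map coords -> fractional source index
    x <- (tc - 0.5) * 2
    y <- 8 - (tr - 0.5) * 2
    cf <- x + 0.5
    rf <- (8 - y) + 0.5
    want <- min(63, max(0, naiveCubicSample(ramp, rf, cf)))
    expect_equal(vo[tr, tc], want, tolerance = 1e-6)
  }
})

test_that("resampling propagates nodata and rejects bad configuration", {
  v <- matrix(5, 4, 4)
  nd <- matrix(FALSE, 4, 4); nd[1, 1] <- TRUE
  r <- LightRaster(v, nodata = nd, geotransform = c(0, 1, 0, 4, 0, -1))
  out <- reprojectResample(r, "cartesian", cellSize = 1, method = "nearest")
  expect_true(nodataMask(out)[1, 1])
  expect_false(any(nodataMask(out)[-1]))
  expect_error(reprojectResample(r, "utm99", cellSize = 1),
               "configuration error")
  empty <- new("LightRaster", values = matrix(numeric(0), 0, 0),
               nodata = matrix(logical(0), 0, 0),
               geotransform = c(0, 1, 0, 0, 0, -1), crs = "cartesian",
               integerDN = TRUE)
  expect_error(reprojectResample(empty, "cartesian", cellSize = 1),
               "input error")
})

test_that("projection round trips through Albers within a metre", {
  lon <- c(80, 100, 120, 105)
  lat <- c(20, 35, 50, 40)
  p <- projectPoints(lon, lat, "wgs84", "albers_china")
  back <- projectPoints(p$x, p$y, "albers_china", "wgs84")
  expect_equal(back$x, lon, tolerance = 1e-8)
  expect_equal(back$y, lat, tolerance = 1e-8)
})

test_that("cell centers inside a square zone are found exactly", {
  v <- matrix(1:25, 5, 5)
  r <- LightRaster(v %% 64, geotransform = c(0, 1, 0, 5, 0, -1))
  z <- ZonePolygons("a", odrlight:::rectRing(1, 1, 4, 4))
  cells <- maskExtract(r, z)
  expect_length(cells[["a"]], 9)
})

test_that("adjacent zones partition cells and boundary ties are
           deterministic", {
  v <- matrix(0, 4, 8)
  r <- LightRaster(v, geotransform = c(0, 1, 0, 4, 0, -1))
  z <- ZonePolygons(c("L", "R"),
                    list(odrlight:::rectRing(0, 0, 4, 4),
                         odrlight:::rectRing(4, 0, 8, 4)))
  cells <- maskExtract(r, z)
  expect_length(intersect(cells$L, cells$R), 0)
  expect_equal(length(cells$L) + length(cells$R), 32)
  # overlapping zones: contested cells go to the first id in sorted order
  z2 <- ZonePolygons(c("B", "A"),
                     list(odrlight:::rectRing(0, 0, 8, 4),
                          odrlight:::rectRing(0, 0, 8, 4)))
  cells2 <- suppressWarnings(maskExtract(r, z2))
  expect_length(cells2$A, 32)
  expect_length(cells2$B, 0)
})

test_that("mask extraction agrees with a winding-number oracle on random
           rectangles", {
  set.seed(42)
  v <- matrix(sample(0:63, 400, replace = TRUE), 20, 20)
  r <- LightRaster(v, geotransform = c(0, 1, 0, 20, 0, -1))
  rects <- list(c(1.2, 2.3, 7.8, 9.1), c(8.4, 0.7, 15.2, 6.6),
                c(3.1, 11.4, 12.9, 18.2), c(14.6, 8.9, 19.4, 16.1))
  z <- ZonePolygons(sprintf("r%d", 1:4),
                    lapply(rects, function(b)
                      odrlight:::rectRing(b[1], b[2], b[3], b[4])))
  cells <- maskExtract(r, z)
  for (zi in 1:4) {
    ring <- zoneGeometry(z)[[zi]][[1]]
    want <- integer(0)
    for (cc in 1:20) for (rr in 1:20) {
      px <- cc - 0.5; py <- 20 - rr + 0.5
      if (windingInside(px, py, ring))
        want <- c(want, (cc - 1) * 20 + rr)
    }
    expect_setequal(cells[[sprintf("r%d", zi)]], want)
  }
})

test_that("a zone outside the raster extent is flagged empty with a
           warning", {
  r <- LightRaster(matrix(1, 3, 3), geotransform = c(0, 1, 0, 3, 0, -1))
  z <- ZonePolygons("far", odrlight:::rectRing(100, 100, 110, 110))
  expect_warning(cells <- maskExtract(r, z), "no usable raster cells")
  expect_length(cells$far, 0)
})

test_that("zonal statistics reproduce hand sums and exhaustive
           accumulation", {
  v <- matrix(0, 3, 3)
  r0 <- LightRaster(v, geotransform = c(0, 1, 0, 3, 0, -1))
  zs0 <- zonalStats(r0, list(z = 1:9))
  expect_equal(zs0$sum_dn, 0)
  expect_equal(zs0$mean_dn, 0)
  expect_equal(zs0$n_pixels, 9)

  v1 <- matrix(c(3, 7, 10, rep(0, 6)), 3, 3)
  r1 <- LightRaster(v1, geotransform = c(0, 1, 0, 3, 0, -1))
  zs1 <- zonalStats(r1, list(z = 1:3))
  expect_equal(zs1$sum_dn, 20)
  expect_equal(zs1$mean_dn, 20 / 3)

  set.seed(7)
  v2 <- matrix(sample(0:63, 100, replace = TRUE), 10, 10)
  r2 <- LightRaster(v2, geotransform = c(0, 1, 0, 10, 0, -1))
  idx <- sample(100, 60)
  zs2 <- zonalStats(r2, list(z = idx))
  acc <- 0
  for (i in idx) acc <- acc + v2[i]   # exhaustive accumulation
  expect_identical(zs2$sum_dn, as.numeric(acc))
})

test_that("province sums equal the sum of their member cities and means
           respect the DN range", {
  set.seed(9)
  cities <- generateLatticeZones(4, 4, cellSize = 1)
  intensity <- setNames(runif(16, 0, 60), zoneIds(cities))
  r <- generateDnRaster(cities, intensity, 25, seed = 3)
  cz <- zonalStats(r, maskExtract(r, cities))
  # one province exactly covering the city lattice
  prov <- ZonePolygons("P1", odrlight:::rectRing(0, 0, 4, 4),
                       level = "province")
  pz <- zonalStats(r, maskExtract(r, prov))
  expect_equal(pz$sum_dn, sum(cz$sum_dn))
  expect_equal(pz$n_pixels, sum(cz$n_pixels))
  v <- rasterValues(r)
  for (k in seq_len(nrow(cz))) {
    cells <- maskExtract(r, cities)[[cz$zone_id[k]]]
    expect_gte(cz$mean_dn[k], min(v[cells]))
    expect_lte(cz$mean_dn[k], max(v[cells]))
    expect_equal(cz$sum_dn[k], cz$mean_dn[k] * cz$n_pixels[k],
                 tolerance = 1e-9)
  }
})

test_that("ASCII grid and GeoJSON round trips preserve content", {
  set.seed(5)
  v <- matrix(sample(0:63, 30, replace = TRUE), 5, 6)
  nd <- matrix(FALSE, 5, 6); nd[2, 3] <- TRUE
  r <- LightRaster(v, nodata = nd, geotransform = c(10, 2, 0, 20, 0, -2))
  f <- tempfile(fileext = ".asc")
  writeAsciiGrid(r, f)
  r2 <- readAsciiGrid(f)
  expect_equal(rasterValues(r2)[!nodataMask(r2)],
               rasterValues(r)[!nodataMask(r)])
  expect_identical(nodataMask(r2), nodataMask(r))
  expect_equal(geoTransform(r2), geoTransform(r))

  z <- generateLatticeZones(2, 3)
  g <- tempfile(fileext = ".geojson")
  writeZonePolygons(z, g)
  z2 <- readZonePolygons(g)
  expect_identical(zoneIds(z2), zoneIds(z))
  expect_equal(zoneGeometry(z2), zoneGeometry(z))
})
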