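test_that("raster sampling uses the containing cell with half-open edges", {
  r <- PaddockRaster(matrix(1:4, 2, 2), cellSize = 5)     # z[row, col]
  expect_equal(sampleRaster(c(2.5, 2.5), r), 1)
  expect_equal(sampleRaster(c(7.5, 2.5), r), 3)
  expect_equal(sampleRaster(c(5, 0), r), 3)               # edge -> eastern cell
  expect_equal(sampleRaster(c(10, 10), r), 4)             # outer max edge
  expect_error(sampleRaster(c(11, 0), r), "outside")
  const <- PaddockRaster(matrix(0.7, 4, 4), cellSize = 2)
  set.seed(71)
  pts <- cbind(runif(50, 0, 8), runif(50, 0, 8))
  expect_true(all(sampleRaster(pts, const) == 0.7))
  # random probes vs index arithmetic
  z <- matrix(rnorm(200), 10, 20)
  ras <- PaddockRaster(z, 100, 50, 5)
  pts2 <- cbind(runif(500, 100, 200 - 1e-9), runif(500, 50, 100 - 1e-9))
  oracle <- z[cbind(floor((pts2[, 2] - 50) / 5) + 1, floor((pts2[, 1] - 100) / 5) + 1)]
  expect_equal(sampleRaster(pts2, ras), oracle)
})

test_that("aspect gives the compass-bearing downslope direction", {
  # plane rising to the north -> water flows due south (180 degrees)
  south <- PaddockRaster(outer(1:6, rep(1, 6)) * 2, cellSize = 5)
  a <- rasterValues(computeAspect(south))
  expect_true(all(a[2:5, 2:5] == 180))
  # plane rising to the east -> downslope due west (270)
  west <- PaddockRaster(outer(rep(1, 6), 1:6) * 2, cellSize = 5)
  expect_true(all(rasterValues(computeAspect(west))[2:5, 2:5] == 270))
  flat <- PaddockRaster(matrix(5, 6, 6), cellSize = 5)
  expect_true(all(is.na(rasterValues(computeAspect(flat)))))
  expect_error(computeAspect(PaddockRaster(matrix(1:4, 2, 2))), "3 x 3")
  # random smooth surface vs an independent Horn stencil oracle
  set.seed(72)
  x <- seq(0, 2 * pi, length.out = 12)
  z <- outer(sin(x), cos(x)) * 10 + outer(x, x) / 2
  ras <- PaddockRaster(z, cellSize = 5)
  got <- rasterValues(computeAspect(ras))
  for (i in c(2, 5, 11)) for (j in c(2, 7, 11)) {
    gx <- ((z[i + 1, j + 1] + 2 * z[i, j + 1] + z[i - 1, j + 1]) -
           (z[i + 1, j - 1] + 2 * z[i, j - 1] + z[i - 1, j - 1])) / (8 * 5)
    gy <- ((z[i + 1, j - 1] + 2 * z[i + 1, j] + z[i + 1, j + 1]) -
           (z[i - 1, j - 1] + 2 * z[i - 1, j] + z[i - 1, j + 1])) / (8 * 5)
    expect_equal(got[i, j], (atan2(-gx, -gy) * 180 / pi) %% 360, tolerance = 1e-6)
  }
})

test_that("IDW interpolation reproduces samples exactly and matches brute force", {
  spec <- buildGrid(unitSquare(20), 5)
  flatS <- data.frame(easting = c(1, 10, 19), northing = c(1, 10, 19), ndvi = 0.25)
  expect_true(all(rasterValues(interpolateNDVI(flatS, spec)) == 0.25))
  # a sample sitting exactly on a cell centre wins outright
  s2 <- data.frame(easting = c(2.5, 1, 19), northing = c(2.5, 18, 3),
                   ndvi = c(0.9, 0.1, 0.2))
  r2 <- interpolateNDVI(s2, spec)
  expect_equal(rasterValues(r2)[1, 1], 0.9)
  set.seed(73)
  s3 <- data.frame(easting = runif(25, 0, 20), northing = runif(25, 0, 20),
                   ndvi = runif(25, 0.1, 0.4))
  r3 <- interpolateNDVI(s3, spec)
  ctr <- cellCenters(spec)
  oracle <- vapply(seq_len(nrow(ctr)), function(i)
    oracleIDW(ctr[i, 1], ctr[i, 2], s3$easting, s3$northing, s3$ndvi), numeric(1))
  expect_equal(as.vector(t(rasterValues(r3))), oracle, tolerance = 1e-12)
  # IDW convexity: bounded by the sample range
  expect_true(all(rasterValues(r3) >= min(s3$ndvi) - 1e-12))
  expect_true(all(rasterValues(r3) <= max(s3$ndvi) + 1e-12))
  expect_error(interpolateNDVI(s3[1:2, ], spec), "3")
})

test_that("the chill index has the right closed form and monotonic structure", {
  expect_equal(windChill(40, 0, 0), 481)
  expect_equal(windChill(10, 3, 0), (11.7 + 3.1 * sqrt(3)) * 30 + 481,
               tolerance = 1e-12)
  set.seed(74)
  t0 <- runif(30, -5, 25); v0 <- runif(30, 0, 15); r0 <- runif(30, 0, 8)
  expect_true(all(windChill(t0 + 1, v0, r0) < windChill(t0, v0, r0)))
  expect_true(all(windChill(t0, v0 + 1, r0) > windChill(t0, v0, r0)))
  expect_true(all(windChill(t0, v0, r0 + 1) > windChill(t0, v0, r0)))
  oracle <- (11.7 + 3.1 * v0^0.5) * (40 - t0) + 481 + 418 * (1 - exp(-0.04 * r0))
  expect_equal(windChill(t0, v0, r0), oracle, tolerance = 1e-12)
  expect_error(windChill(NA, 1, 0), "finite")
  # pluggable formula
  expect_equal(windChill(5, 2, 1, formula = function(t, v, r) t + v + r), 8)
})

test_that("weather joins by flooring to the hour and reports gaps", {
  start <- as.POSIXct("2014-04-23 00:00:00", tz = "UTC")
  wx <- data.frame(timestamp = start + (0:23) * 3600,
                   temp_c = 1:24, rain_mm = 0, wind_ms = 2)
  rows <- data.frame(timestamp = start + c(30 * 60, 10.5 * 3600))
  got <- joinWeather(rows, wx)
  expect_equal(got$T, c(1, 11))                       # 00:30 -> hour 00, 10:30 -> 10
  expect_equal(got$WC, windChill(got$T, 2, 0))
  gap <- data.frame(timestamp = start + 30 * 3600)
  expect_error(joinWeather(gap, wx), "cover")
  set.seed(75)
  rows2 <- data.frame(timestamp = start + runif(200, 0, 24 * 3600 - 1))
  oracle <- wx$temp_c[floor(as.numeric(rows2$timestamp - start, units = "secs") / 3600) + 1]
  expect_equal(joinWeather(rows2, wx)$T, oracle)
})

test_that("VIF screening matches 1/(1-R2), car::vif, and drops collinear columns", {
  set.seed(76)
  n <- 300
  ortho <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  v <- vifFilter(ortho)
  expect_setequal(v$retained, c("x1", "x2", "x3"))
  expect_true(all(v$vif < 1.2))
  # correlated pair: VIF equals the textbook formula via explicit regression
  z <- rnorm(n)
  cor2 <- data.frame(a = z + rnorm(n, 0, 0.14), b = z + rnorm(n, 0, 0.14),
                     c = rnorm(n))
  r2 <- summary(lm(a ~ b + c, data = cor2))$r.squared
  vifs <- vifFilter(cor2, threshold = Inf)$vif
  expect_equal(unname(vifs["a"]), 1 / (1 - r2), tolerance = 1e-9)
  if (requireNamespace("car", quietly = TRUE)) {
    y <- rnorm(n)
    carVif <- car::vif(lm(y ~ a + b + c, data = cor2))
    expect_equal(unname(vifs[names(carVif)]), unname(carVif), tolerance = 1e-6)
  }
  # exact collinearity: one of the set is dropped, survivors below threshold
  tri <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  tri$x3 <- tri$x1 + tri$x2
  out <- vifFilter(tri)
  expect_equal(length(out$dropped), 1)
  expect_true(all(out$vif < 5))
  expect_error(vifFilter(data.frame(x1 = rnorm(n), k = rep(1, n))), "constant")
})

test_that("the assembled model table matches per-fix recomputation", {
  st <- tinyStudy()
  res <- computeLRI(st$fixes, st$spec)
  tab <- assembleModelTable(st$fixes, res, st$landscape, st$weather)
  expect_true(all(modelPredictors() %in% names(tab)))
  expect_equal(ncol(tab), 15)                         # timestamp, hour, 12, LRI
  rep <- attr(tab, "dropReport")
  expect_equal(rep$nRetained, nrow(tab))
  # column-wise equality with an independent per-fix recomputation
  set.seed(77)
  asp <- computeAspect(st$landscape@elevation)
  idx <- sample(nrow(tab), 25)
  for (i in idx) {
    p <- c(tab$EA[i], tab$NO[i])
    expect_equal(tab$NT[i], min(sqrt((p[1] - st$landscape@trees[, 1])^2 +
                                     (p[2] - st$landscape@trees[, 2])^2)))
    expect_equal(tab$NDVI[i], sampleRaster(p, st$landscape@ndvi))
    expect_equal(tab$EL[i], sampleRaster(p, st$landscape@elevation))
    expect_equal(tab$AS[i], sampleRaster(p, asp))
    hr <- floor(as.numeric(difftime(tab$timestamp[i], st$cfg$trialStart,
                                    units = "hours"))) + 1
    expect_equal(tab$T[i], st$weather$temp_c[hr])
  }
  # rows with undefined covariates are dropped with a per-cause count
  holey <- st$landscape
  nv <- rasterValues(holey@ndvi); nv[, 1:10] <- NA
  holey@ndvi <- PaddockRaster(nv, 0, 0, st$cfg$cellSize)
  tab2 <- assembleModelTable(st$fixes, res, holey, st$weather)
  rep2 <- attr(tab2, "dropReport")
  expect_gt(rep2$missingNDVI, 0)
  expect_equal(rep2$nRetained + rep2$missingNDVI + rep2$flatOrMissingAspect +
                 rep2$undefinedLRI, rep2$nInput)
  expect_false(anyNA(tab2$NDVI))
})
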