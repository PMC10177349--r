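# brute-force cell-polygon intersection oracle for grid masks
oracleMask <- function(spec, ring) {
  segInt <- function(p1, p2, p3, p4) {
    d1 <- p2 - p1; d2 <- p4 - p3
    den <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(den) < 1e-12) return(FALSE)
    t <- ((p3 - p1)[1] * d2[2] - (p3 - p1)[2] * d2[1]) / den
    u <- ((p3 - p1)[1] * d1[2] - (p3 - p1)[2] * d1[1]) / den
    t >= -1e-12 && t <= 1 + 1e-12 && u >= -1e-12 && u <= 1 + 1e-12
  }
  d <- gridDim(spec); o <- gridOrigin(spec); s <- cellSize(spec)
  m <- matrix(FALSE, d[["nRows"]], d[["nCols"]])
  for (r in seq_len(d[["nRows"]])) for (cc in seq_len(d[["nCols"]])) {
    x0 <- o[["x"]] + (cc - 1) * s; y0 <- o[["y"]] + (r - 1) * s
    corners <- rbind(c(x0, y0), c(x0 + s, y0), c(x0 + s, y0 + s), c(x0, y0 + s))
    hit <- any(oracleInPolygon(corners[, 1], corners[, 2], ring)) ||
      any(ring[, 1] >= x0 & ring[, 1] <= x0 + s &
          ring[, 2] >= y0 & ring[, 2] <= y0 + s)
    if (!hit) {
      cellEdges <- rbind(cbind(corners, corners[c(2, 3, 4, 1), ]))
      for (k in seq_len(nrow(ring) - 1)) for (e in 1:4) {
        if (segInt(ring[k, ], ring[k + 1, ], cellEdges[e, 1:2], cellEdges[e, 3:4])) {
          hit <- TRUE; break
        }
      }
    }
    m[r, cc] <- hit
  }
  m
}

test_that("grid construction snaps the origin and masks intersecting cells", {
  g <- buildGrid(unitSquare(10))
  expect_equal(unname(gridDim(g)), c(2L, 2L))
  expect_true(all(gridMask(g)))
  shifted <- PaddockBoundary(cbind(c(2.5, 12.5, 12.5, 2.5), c(2.5, 2.5, 12.5, 12.5)))
  g2 <- buildGrid(shifted)
  expect_equal(unname(gridOrigin(g2)), c(0, 0))
  expect_equal(unname(gridDim(g2)), c(3L, 3L))
  expect_true(all(gridMask(g2)))                      # every cell clips the square
  expect_equal(gridMask(g2), oracleMask(g2, boundaryRing(shifted)))
  # offset diamond on a finer grid: bbox corner cells have empty intersection
  diam <- PaddockBoundary(cbind(c(5, 9.5, 5, 0.5), c(0.5, 5, 9.5, 5)))
  g3 <- buildGrid(diam, 2.5)
  expect_false(gridMask(g3)[1, 1])                    # masked out
  expect_true(gridMask(g3)[2, 2])
  expect_equal(gridMask(g3), oracleMask(g3, boundaryRing(diam)))
})

test_that("grid mask matches the brute-force oracle on an irregular paddock", {
  ring <- cbind(c(1, 33, 41, 22, -6, 1), c(2, -4, 20, 37, 18, 2))
  poly <- PaddockBoundary(ring)
  g <- buildGrid(poly, 5)
  expect_equal(gridMask(g), oracleMask(g, boundaryRing(poly)))
})

test_that("fixToCell follows the half-open convention and a floor oracle", {
  g <- buildGrid(unitSquare(10))
  expect_equal(fixToCell(c(2.5, 2.5), g)$cell, 1L)
  expect_equal(unlist(fixToCell(c(5, 0), g)[, c("col", "row")]),
               c(col = 2L, row = 1L))                 # edge point goes north-east
  expect_equal(unlist(fixToCell(c(10, 10), g)[, c("col", "row")]),
               c(col = 2L, row = 2L))                 # extent max edge: last cell
  set.seed(61)
  pts <- cbind(runif(1000, 0, 10 - 1e-9), runif(1000, 0, 10 - 1e-9))
  got <- fixToCell(pts, g)
  expect_equal(got$col, as.integer(floor(pts[, 1] / 5)) + 1L)
  expect_equal(got$row, as.integer(floor(pts[, 2] / 5)) + 1L)
  expect_error(fixToCell(c(-1, 5), g), "outside")
})

test_that("LRI conserves mass, honours symmetry, and matches a count oracle", {
  start <- as.POSIXct("2014-04-23", tz = "UTC")
  g <- buildGrid(unitSquare(10))
  one <- makeFixes(60, easting = rep(2, 60), northing = rep(2, 60), spacing = 60)
  one <- assignHours(one, start)
  res <- computeLRI(one, g)
  expect_equal(lriValues(res)[1, 1], 1)               # all mass in one cell
  expect_equal(sum(lriValues(res)[, 1]), 1)
  four <- makeFixes(60, easting = rep(c(2, 7, 2, 7), 15),
                    northing = rep(c(2, 2, 7, 7), 15), spacing = 60)
  four <- assignHours(four, start)
  expect_equal(sort(lriValues(computeLRI(four, g))[, 1]), rep(0.25, 4))
  # 15 animals random scatter vs brute-force count/total oracle
  set.seed(62)
  fx <- do.call(rbind, lapply(sprintf("A%02d", 1:15), function(id)
    makeFixes(80, id, easting = runif(80, 0, 9.99), northing = runif(80, 0, 9.99),
              spacing = 45)))
  fx <- assignHours(fx, start)
  res2 <- computeLRI(fx, g)
  cells <- fixToCell(fx, g)$cell
  for (h in unique(fx$hour)) {
    sel <- fx$hour == h
    oracle <- table(factor(cells[sel], levels = 1:4)) / sum(sel)
    expect_equal(lriValues(res2)[, h], as.vector(oracle), tolerance = 1e-12)
    expect_equal(sum(lriValues(res2)[, h]), 1, tolerance = 1e-9)
  }
  # permuting animal order leaves the treatment LRI unchanged
  perm <- fx[order(rev(fx$animal_id), fx$timestamp), ]
  expect_equal(lriValues(computeLRI(perm, g)), lriValues(res2))
})

test_that("refining the grid partitions each parent cell's counts", {
  start <- as.POSIXct("2014-04-23", tz = "UTC")
  b <- unitSquare(10)
  set.seed(63)
  fx <- assignHours(makeFixes(500, easting = runif(500, 0, 9.99),
                              northing = runif(500, 0, 9.99), spacing = 5), start)
  coarse <- computeLRI(fx, buildGrid(b, 5))
  fine <- computeLRI(fx, buildGrid(b, 2.5))
  cf <- rowSums(lriCounts(coarse)); ff <- rowSums(lriCounts(fine))
  # parent (row r, col c) at 5 m covers fine cells (2r-1,2r) x (2c-1,2c)
  for (r in 1:2) for (cc in 1:2) {
    parent <- cf[(r - 1) * 2 + cc]
    kids <- outer(2 * r - c(1, 0), (2 * cc - c(1, 0)) , function(rr, ccc)
      ff[(rr - 1) * 4 + ccc])
    expect_equal(parent, sum(kids))
  }
})

test_that("hours without fixes are undefined, and per-fix lookup matches the grid", {
  start <- as.POSIXct("2014-04-23", tz = "UTC")
  g <- buildGrid(unitSquare(10))
  fx <- makeFixes(10, easting = rep(2, 10), northing = rep(2, 10), spacing = 60)
  fx$timestamp[6:10] <- fx$timestamp[6:10] + 2 * 3600   # skip hour 2 entirely
  fx <- assignHours(fx, start)
  res <- computeLRI(fx, g)
  expect_true(all(is.na(lriValues(res)[, 2])))        # empty hour is NA, not 0
  expect_equal(lriAtFix(fx, res), rep(1, 10))
  # an unvisited cell yields 0 for a fix placed there in a defined hour
  probe <- fx[1, ]; probe$easting <- 7; probe$northing <- 7
  expect_equal(lriAtFix(probe, res), 0)
  probe2 <- fx[1, ]; probe2$hour <- 2L
  expect_true(is.na(lriAtFix(probe2, res)))
  # full-table lookup equals direct matrix indexing
  set.seed(64)
  fx2 <- assignHours(makeFixes(300, easting = runif(300, 0, 9.99),
                               northing = runif(300, 0, 9.99), spacing = 20), start)
  res2 <- computeLRI(fx2, g)
  cells <- fixToCell(fx2, g)$cell
  expect_equal(lriAtFix(fx2, res2),
               lriValues(res2)[cbind(cells, fx2$hour)])
})

test_that("animal-level LRI uses only that animal's fixes", {
  start <- as.POSIXct("2014-04-23", tz = "UTC")
  g <- buildGrid(unitSquare(10))
  fx <- rbind(makeFixes(20, "a", easting = rep(2, 20), northing = rep(2, 20), spacing = 60),
              makeFixes(20, "b", easting = rep(7, 20), northing = rep(7, 20), spacing = 60))
  fx <- assignHours(fx, start)
  resA <- computeLRI(fx, g, level = "animal", animal = "a")
  expect_equal(lriValues(resA)[1, 1], 1)
  expect_equal(sum(lriCounts(resA)), 20)
  expect_error(computeLRI(fx, g, level = "animal"), "animal id")
})

test_that("residency export round-trips through raster and table", {
  start <- as.POSIXct("2014-04-23", tz = "UTC")
  g <- buildGrid(unitSquare(10))
  set.seed(65)
  fx <- assignHours(makeFixes(200, easting = runif(200, 0, 9.99),
                              northing = runif(200, 0, 9.99), spacing = 30), start)
  res <- computeLRI(fx, g)
  paths <- exportResidency(res, file.path(tempdir(), "res"))
  ras <- readAsciiGrid(paths[["raster"]])
  agg <- matrix(aggregateLRI(res), 2, 2, byrow = TRUE)
  expect_equal(rasterValues(ras), agg, tolerance = 1e-12)
  tab <- read.csv(paths[["table"]])
  expect_equal(nrow(tab), 4 * length(res@hours))
  # table cell order matches the row-major convention
  lookup <- tab[tab$hour == 1, ]
  expect_equal(lookup$lri[order(lookup$cell_id)], lriValues(res)[, 1])
})
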