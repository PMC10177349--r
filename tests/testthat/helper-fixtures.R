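# Shared fixture builders and independent brute-force oracles. Oracles are
# written naively (per-element loops, direct formulas) on purpose: they must
# not share code paths with the implementation they check.

unitSquare <- function(side = 1, name = "sq")
  PaddockBoundary(cbind(c(0, side, side, 0), c(0, 0, side, side)), name)

makeFixes <- function(n, animal = "a", start = as.POSIXct("2014-04-23", tz = "UTC"),
                      easting = NULL, northing = NULL, ttf = NULL, spacing = 15) {
  data.frame(animal_id = rep(animal, length.out = n),
             timestamp = start + (seq_len(n) - 1) * spacing,
             easting = easting %||% runif(n, 0, 10),
             northing = northing %||% runif(n, 0, 10),
             ttf = ttf %||% runif(n, 2, 10),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# slow point-in-polygon by ray casting, with on-edge detection
oracleInPolygon <- function(px, py, ring, eps = 1e-12) {
  n <- nrow(ring) - 1
  vapply(seq_along(px), function(i) {
    x <- px[i]; y <- py[i]
    inside <- FALSE
    for (k in seq_len(n)) {
      x1 <- ring[k, 1]; y1 <- ring[k, 2]; x2 <- ring[k + 1, 1]; y2 <- ring[k + 1, 2]
      # on-edge?
      cross <- (x - x1) * (y2 - y1) - (y - y1) * (x2 - x1)
      if (abs(cross) < eps &&
          x >= min(x1, x2) - eps && x <= max(x1, x2) + eps &&
          y >= min(y1, y2) - eps && y <= max(y1, y2) + eps) return(TRUE)
      if ((y1 > y) != (y2 > y) &&
          x < (x2 - x1) * (y - y1) / (y2 - y1) + x1) inside <- !inside
    }
    inside
  }, logical(1))
}

# naive min distance from one point to a set of segments
oracleSegmentDistance <- function(x, y, segs) {
  best <- Inf
  for (k in seq_len(nrow(segs))) {
    ax <- segs[k, 1]; ay <- segs[k, 2]; bx <- segs[k, 3]; by <- segs[k, 4]
    L2 <- (bx - ax)^2 + (by - ay)^2
    t <- if (L2 == 0) 0 else max(0, min(1, ((x - ax) * (bx - ax) + (y - ay) * (by - ay)) / L2))
    px <- ax + t * (bx - ax); py <- ay + t * (by - ay)
    best <- min(best, sqrt((x - px)^2 + (y - py)^2))
  }
  best
}

# naive IDW (all neighbours, power p) at one location
oracleIDW <- function(x, y, sx, sy, sv, p = 2) {
  d <- sqrt((x - sx)^2 + (y - sy)^2)
  if (any(d == 0)) return(sv[which(d == 0)[1]])
  w <- 1 / d^p
  sum(w * sv) / sum(w)
}

# a tiny deterministic landscape + weather + fixes for covariate tests
tinyStudy <- function(seed = 5, nDays = 1, nAnimals = 4) {
  cfg <- simConfig(seed = seed, nDays = nDays, nAnimals = nAnimals,
                   paddockWidth = 200, paddockHeight = 150, nTrees = 8,
                   driverWeights = list(grazing = c(ndvi = 2)))
  landscape <- generateLandscape(cfg)
  weather <- generateWeather(cfg)
  truth <- simulateFlock(landscape, weather, cfg)
  raw <- observeGps(truth, cfg)
  fixes <- assignHours(cleanFixes(raw, landscape@boundary), cfg$trialStart)
  spec <- buildGrid(landscape@boundary, cfg$cellSize)
  list(cfg = cfg, landscape = landscape, weather = weather, truth = truth,
       raw = raw, fixes = fixes, spec = spec)
}
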