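# Planar geometry on projected coordinates (metres).

# Shoelace signed area of a closed ring (n x 2, first == last vertex).
.polygonArea <- function(ring) {
  x <- ring[, 1L]; y <- ring[, 2L]
  n <- length(x)
  sum(x[-n] * y[-1L] - x[-1L] * y[-n]) / 2
}

# Proper/improper intersection of segments p1-p2 and p3-p4 (excluding the
# shared-endpoint contacts of consecutive ring edges, handled by the caller).
.segmentsIntersect <- function(p1, p2, p3, p4, eps = 1e-12) {
  d1 <- p2 - p1; d2 <- p4 - p3
  den <- d1[1L] * d2[2L] - d1[2L] * d2[1L]
  w <- p3 - p1
  if (abs(den) < eps) {                       # parallel: overlap check
    if (abs(w[1L] * d1[2L] - w[2L] * d1[1L]) > eps) return(FALSE)
    L2 <- sum(d1^2)
    if (L2 < eps) return(FALSE)
    t3 <- sum((p3 - p1) * d1) / L2
    t4 <- sum((p4 - p1) * d1) / L2
    return(max(min(t3, t4), 0) <= min(max(t3, t4), 1) - eps)
  }
  t <- (w[1L] * d2[2L] - w[2L] * d2[1L]) / den
  u <- (w[1L] * d1[2L] - w[2L] * d1[1L]) / den
  t > eps && t < 1 - eps && u > eps && u < 1 - eps
}

# Does a closed ring self-intersect (non-adjacent edge pairs)?
.ringSelfIntersects <- function(ring) {
  n <- nrow(ring) - 1L                        # edges 1..n, edge i = ring[i] -> ring[i+1]
  if (n < 4L) return(FALSE)
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n        # skip adjacent (and first-last) pairs
    for (j in (i + 2L):jmax) {
      if (.segmentsIntersect(ring[i, ], ring[i + 1L, ], ring[j, ], ring[j + 1L, ]))
        return(TRUE)
    }
  }
  FALSE
}

#' Point-in-paddock test
#'
#' Tests whether points lie inside or on a paddock boundary. Points exactly
#' on the ring count as inside, so fence-line fixes survive cleaning.
#'
#' @param easting,northing numeric vectors of projected coordinates (m).
#' @param boundary a [PaddockBoundary-class].
#' @return Logical vector.
#' @examples
#' b <- PaddockBoundary(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
#' insidePaddock(c(0.5, 2, 1), c(0.5, 0.5, 1), b)
#' @export
insidePaddock <- function(easting, northing, boundary) {
  stopifnot(is(boundary, "PaddockBoundary"))
  ring <- boundaryRing(boundary)
  pracma::inpolygon(easting, northing, ring[, 1L], ring[, 2L], boundary = TRUE)
}

#' Minimum distance to landscape features
#'
#' Euclidean near distance from query points to the closest member of a
#' feature set: a point layer (trees, water troughs) or a polyline layer
#' (fence lines), matching the NT/NW/NF covariates.
#'
#' @param points numeric n x 2 matrix (or length-2 vector) of query
#'   coordinates in metres.
#' @param features either an m x 2 matrix of feature points, or a list of
#'   n_i x 2 matrices interpreted as polylines (distance to the nearest
#'   segment).
#' @return Numeric vector of distances (m), one per query point.
#' @examples
#' nearDistance(c(3, 4), rbind(c(0, 0)))           # 5
#' nearDistance(c(0, 1), list(rbind(c(-1, 0), c(1, 0))))  # 1, to a segment
#' @export
nearDistance <- function(points, features) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2L)
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2L, all(is.finite(points)))
  if (is.list(features) && !is.data.frame(features)) {
    segs <- do.call(rbind, lapply(features, .polylineSegments))
    if (is.null(segs) || nrow(segs) == 0L) stop("empty feature set")
    return(.pointSegmentDistance(points, segs))
  }
  features <- as.matrix(features)
  if (nrow(features) == 0L) stop("empty feature set")
  stopifnot(ncol(features) == 2L, all(is.finite(features)))
  # chunked pairwise distances to bound memory on large fix tables
  out <- numeric(nrow(points))
  idx <- seq_len(nrow(points))
  for (chunk in split(idx, ceiling(idx / 20000L))) {
    dx <- outer(points[chunk, 1L], features[, 1L], "-")
    dy <- outer(points[chunk, 2L], features[, 2L], "-")
    out[chunk] <- sqrt(.rowMins(dx * dx + dy * dy))
  }
  out
}

.rowMins <- function(m) {
  if (ncol(m) == 1L) as.vector(m) else do.call(pmin, as.data.frame(m))
}

# polyline (n x 2) -> segment table (x0, y0, x1, y1)
.polylineSegments <- function(line) {
  line <- as.matrix(line)
  n <- nrow(line)
  if (n < 2L) return(NULL)
  cbind(line[-n, 1L], line[-n, 2L], line[-1L, 1L], line[-1L, 2L])
}

# min distance from each point to any segment; vectorised over segments
.pointSegmentDistance <- function(points, segs) {
  out <- rep(Inf, nrow(points))
  for (k in seq_len(nrow(segs))) {
    ax <- segs[k, 1L]; ay <- segs[k, 2L]
    dx <- segs[k, 3L] - ax; dy <- segs[k, 4L] - ay
    L2 <- dx * dx + dy * dy
    if (L2 == 0) {
      d2 <- (points[, 1L] - ax)^2 + (points[, 2L] - ay)^2
    } else {
      t <- pmin(pmax(((points[, 1L] - ax) * dx + (points[, 2L] - ay) * dy) / L2, 0), 1)
      d2 <- (points[, 1L] - (ax + t * dx))^2 + (points[, 2L] - (ay + t * dy))^2
    }
    out <- pmin(out, d2)
  }
  sqrt(out)
}

# Exact set of grid cells (col,row, 1-based) touched by a segment, by
# parametric traversal of the vertical/horizontal grid lines (supercover).
# Works in grid units relative to the origin.
.cellsOnSegment <- function(x0, y0, x1, y1, originX, originY, cellSize, nCols, nRows) {
  gx0 <- (x0 - originX) / cellSize; gx1 <- (x1 - originX) / cellSize
  gy0 <- (y0 - originY) / cellSize; gy1 <- (y1 - originY) / cellSize
  crossings <- function(a, b) {
    if (a == b) return(numeric(0))
    lo <- ceiling(min(a, b)); hi <- floor(max(a, b))
    if (lo > hi) return(numeric(0))
    ((lo:hi) - a) / (b - a)
  }
  t <- sort(unique(pmin(pmax(c(0, 1, crossings(gx0, gx1), crossings(gy0, gy1)), 0), 1)))
  tm <- c((t[-length(t)] + t[-1L]) / 2, 0, 1)    # sub-span midpoints + endpoints
  clamp <- function(i, n) pmin(pmax(i, 1L), n)
  cols <- clamp(as.integer(floor(gx0 + tm * (gx1 - gx0))) + 1L, nCols)
  rows <- clamp(as.integer(floor(gy0 + tm * (gy1 - gy0))) + 1L, nRows)
  unique(cbind(col = cols, row = rows))
}
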