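# Raster sampling, terrain aspect, IDW interpolation, ESRI ASCII grid IO.

# (col,row) of containing cell under the half-open convention; points exactly
# on the max edge of the extent are assigned to the last cell.
.rasterIndex <- function(raster, easting, northing) {
  s <- cellSize(raster); o <- gridOrigin(raster); d <- gridDim(raster)
  col <- floor((easting - o["x"]) / s) + 1
  row <- floor((northing - o["y"]) / s) + 1
  onXMax <- easting == o["x"] + d["nCols"] * s
  onYMax <- northing == o["y"] + d["nRows"] * s
  col[onXMax] <- d["nCols"]; row[onYMax] <- d["nRows"]
  bad <- col < 1 | col > d["nCols"] | row < 1 | row > d["nRows"]
  if (any(bad)) stop(sprintf("%d point(s) outside raster extent", sum(bad)))
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Sample a raster at point locations
#'
#' Nearest-cell (containing-cell) lookup with half-open cell edges: a point
#' on a shared edge belongs to the cell to its north-east, and points on the
#' raster's outer max edge fall in the last cell. Nodata cells yield `NA`.
#'
#' @param points n x 2 matrix (or length-2 vector) of coordinates in metres.
#' @param raster a [PaddockRaster-class].
#' @return Numeric vector of cell values (`NA` where nodata).
#' @examples
#' r <- PaddockRaster(matrix(1:4, 2, 2), cellSize = 5)
#' sampleRaster(c(7.5, 2.5), r)  # column 2, row 1 -> 3
#' @export
sampleRaster <- function(points, raster) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2L)
  points <- as.matrix(points)
  idx <- .rasterIndex(raster, points[, 1L], points[, 2L])
  rasterValues(raster)[idx]
}

#' Terrain aspect from an elevation raster
#'
#' Downslope azimuth in degrees (0 = north, clockwise) from Horn's 3 x 3
#' finite-difference gradients. Cells whose gradient magnitude falls below
#' `flatTol` are flat and flagged `NA` (the covariate table later drops
#' rows sampled there); border cells lack a full 3 x 3 window and are `NA`.
#'
#' @param elevation a [PaddockRaster-class] of elevation (m ASL), at least
#'   3 x 3 cells.
#' @param flatTol gradient-magnitude tolerance (m/m) below which a cell is
#'   flat.
#' @return A [PaddockRaster-class] of aspect in degrees `[0, 360)`.
#' @examples
#' # plane dipping due south (elevation increases with northing)
#' z <- PaddockRaster(outer(1:5, rep(1, 5)) * 2, cellSize = 5)
#' table(rasterValues(computeAspect(z)))  # 180 everywhere in the interior
#' @export
computeAspect <- function(elevation, flatTol = 1e-8) {
  z <- rasterValues(elevation)
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 3L || nc < 3L) stop("elevation raster must be at least 3 x 3")
  s <- cellSize(elevation)
  asp <- matrix(NA_real_, nr, nc)
  i <- 2:(nr - 1L); j <- 2:(nc - 1L)
  # rows index northing from the south: row i+1 is the northern neighbour
  zNW <- z[i + 1L, j - 1L]; zN <- z[i + 1L, j]; zNE <- z[i + 1L, j + 1L]
  zW  <- z[i, j - 1L];                         zE  <- z[i, j + 1L]
  zSW <- z[i - 1L, j - 1L]; zS <- z[i - 1L, j]; zSE <- z[i - 1L, j + 1L]
  gx <- ((zNE + 2 * zE + zSE) - (zNW + 2 * zW + zSW)) / (8 * s)  # d z / d easting
  gy <- ((zNW + 2 * zN + zNE) - (zSW + 2 * zS + zSE)) / (8 * s)  # d z / d northing
  mag <- sqrt(gx^2 + gy^2)
  a <- (atan2(-gx, -gy) * 180 / pi) %% 360     # azimuth of the downslope vector
  a[mag < flatTol | !is.finite(mag)] <- NA_real_
  asp[i, j] <- a
  PaddockRaster(asp, gridOrigin(elevation)["x"], gridOrigin(elevation)["y"], s)
}

#' Inverse-distance-weighted NDVI surface
#'
#' Interpolates transect NDVI samples onto the paddock grid by inverse
#' distance weighting: the value at a cell centre is the weighted mean of
#' the `k` nearest samples with weights `1/d^power`. A cell centre that
#' coincides with a sample returns that sample's value exactly. Cells
#' outside the paddock mask are `NA`.
#'
#' @param samples data.frame with columns `easting`, `northing`, `ndvi`
#'   (at least 3 rows).
#' @param spec a [GridSpec-class] from [buildGrid()].
#' @param power IDW exponent (default 2).
#' @param k number of neighbours; `Inf` (default) uses all samples.
#' @return A [PaddockRaster-class] of NDVI on `spec`'s grid.
#' @export
interpolateNDVI <- function(samples, spec, power = 2, k = Inf) {
  samples <- as.data.frame(samples)
  stopifnot(all(c("easting", "northing", "ndvi") %in% names(samples)))
  if (nrow(samples) < 3L) stop("need at least 3 NDVI samples to interpolate")
  ctr <- cellCenters(spec)
  mask <- t(gridMask(spec))                    # transpose -> row-major cell order
  vals <- rep(NA_real_, nrow(ctr))
  use <- which(as.vector(mask))
  sx <- samples$easting; sy <- samples$northing; sv <- samples$ndvi
  for (chunk in split(use, ceiling(seq_along(use) / 5000L))) {
    d2 <- outer(ctr[chunk, 1L], sx, "-")^2 + outer(ctr[chunk, 2L], sy, "-")^2
    d <- sqrt(d2)
    w <- 1 / d^power
    if (is.finite(k) && k < length(sv)) {
      keep <- t(apply(d, 1L, function(r) rank(r, ties.method = "first") <= k))
      w[!keep] <- 0
    }
    est <- as.vector((w %*% sv) / rowSums(w))
    exact <- which(d == 0, arr.ind = TRUE)     # zero distance: take the sample
    if (nrow(exact)) est[exact[, 1L]] <- sv[exact[, 2L]]
    vals[chunk] <- est
  }
  d <- gridDim(spec)
  m <- matrix(vals, nrow = d["nRows"], ncol = d["nCols"], byrow = TRUE)
  PaddockRaster(m, gridOrigin(spec)["x"], gridOrigin(spec)["y"], cellSize(spec))
}

#' Write / read a raster as an ESRI ASCII grid
#'
#' Plain-text single-band raster exchange format (`ncols`/`nrows` header,
#' rows written north to south). `NA` is written as the nodata value.
#'
#' @param raster a [PaddockRaster-class].
#' @param path file path.
#' @param nodata nodata sentinel written for `NA` cells.
#' @return `writeAsciiGrid` returns `path` invisibly; `readAsciiGrid`
#'   returns a [PaddockRaster-class].
#' @export
writeAsciiGrid <- function(raster, path, nodata = -9999) {
  v <- rasterValues(raster)
  o <- gridOrigin(raster)
  hdr <- c(sprintf("ncols %d", ncol(v)), sprintf("nrows %d", nrow(v)),
           sprintf("xllcorner %.10g", o["x"]), sprintf("yllcorner %.10g", o["y"]),
           sprintf("cellsize %.10g", cellSize(raster)),
           sprintf("NODATA_value %g", nodata))
  body <- v[rev(seq_len(nrow(v))), , drop = FALSE]   # north row first
  body[is.na(body)] <- nodata
  lines <- apply(body, 1L, function(r) paste(format(r, digits = 15, trim = TRUE,
                                                    scientific = FALSE),
                                             collapse = " "))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' @rdname writeAsciiGrid
#' @export
readAsciiGrid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(tolower(lines[1:6]), "\\s+")
  kv <- stats::setNames(vapply(hdr, function(h) as.numeric(h[2L]), numeric(1L)),
                        vapply(hdr, `[`, character(1L), 1L))
  nc <- as.integer(kv[["ncols"]]); nr <- as.integer(kv[["nrows"]])
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == kv[["nodata_value"]]] <- NA_real_
  m <- m[rev(seq_len(nr)), , drop = FALSE]           # back to south-first rows
  PaddockRaster(m, kv[["xllcorner"]], kv[["yllcorner"]], kv[["cellsize"]])
}
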