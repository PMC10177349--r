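# Central S4 containers: paddock geometry, grids, rasters, residency and fits.

#' @include AllGenerics.R
NULL

#' Paddock boundary polygon
#'
#' A closed, non-self-intersecting ring of projected vertices (metres)
#' delimiting a fenced paddock. Fixes outside the ring are discarded during
#' cleaning; fixes exactly on the ring are retained, because fence-line
#' residency is a real behaviour (sheep camp along fences).
#'
#' @slot ring numeric matrix (n x 2, columns easting/northing, metres); the
#'   first and last vertex coincide.
#' @slot name single character label.
#' @export
setClass("PaddockBoundary",
  representation(ring = "matrix", name = "character"))

setValidity("PaddockBoundary", function(object) {
  r <- object@ring
  if (!is.numeric(r) || ncol(r) != 2L) return("ring must be a numeric n x 2 matrix")
  if (nrow(r) < 4L) return("ring needs at least 4 vertices (closed triangle)")
  if (!all(is.finite(r))) return("ring vertices must be finite")
  if (!isTRUE(all.equal(r[1L, ], r[nrow(r), ], check.attributes = FALSE)))
    return("ring must be closed (first vertex == last vertex)")
  if (abs(.polygonArea(r)) <= 0) return("ring must enclose positive area")
  if (.ringSelfIntersects(r)) return("ring must not self-intersect")
  if (length(object@name) != 1L) return("name must be a single string")
  TRUE
})

#' Construct a paddock boundary
#'
#' @param ring numeric n x 2 matrix of vertices (easting, northing in metres).
#'   Closed automatically if the last vertex differs from the first.
#' @param name label for the paddock.
#' @return A [PaddockBoundary-class] object.
#' @examples
#' b <- PaddockBoundary(cbind(c(0, 100, 100, 0), c(0, 0, 80, 80)), "demo")
#' paddockArea(b)
#' @export
PaddockBoundary <- function(ring, name = "paddock") {
  ring <- as.matrix(ring)
  storage.mode(ring) <- "double"
  colnames(ring) <- c("easting", "northing")
  if (!isTRUE(all.equal(ring[1L, ], ring[nrow(ring), ], check.attributes = FALSE)))
    ring <- rbind(ring, ring[1L, , drop = FALSE])
  new("PaddockBoundary", ring = ring, name = as.character(name))
}

#' @describeIn PaddockBoundary ring vertices as a matrix
#' @param x a `PaddockBoundary`
#' @export
setMethod("boundaryRing", "PaddockBoundary", function(x) x@ring)

#' @describeIn PaddockBoundary enclosed area in square metres
#' @export
setMethod("paddockArea", "PaddockBoundary", function(x) abs(.polygonArea(x@ring)))

setMethod("show", "PaddockBoundary", function(object) {
  bb <- apply(object@ring, 2L, range)
  cat(sprintf("PaddockBoundary '%s': %d vertices, %.2f ha, bbox [%.1f, %.1f] x [%.1f, %.1f] m\n",
              object@name, nrow(object@ring) - 1L, paddockArea(object) / 1e4,
              bb[1L, 1L], bb[2L, 1L], bb[1L, 2L], bb[2L, 2L]))
})

#' Regular grid over a paddock
#'
#' Axis-aligned grid of square cells (default 5 m) whose origin is snapped
#' down to a multiple of the cell size. Cells are half-open
#' `[x, x + s) x [y, y + s)`; the mask records which cells intersect the
#' paddock polygon. Rows index northing from the south edge, columns index
#' easting from the west edge; cell ids run row-major,
#' `id = (row - 1) * nCols + col`.
#'
#' @slot originX,originY south-west corner of cell (1,1), metres.
#' @slot cellSize cell edge, metres.
#' @slot nCols,nRows grid extent in cells.
#' @slot mask logical nRows x nCols matrix, TRUE where the cell intersects
#'   the paddock.
#' @seealso [buildGrid()], [fixToCell()]
#' @export
setClass("GridSpec",
  representation(originX = "numeric", originY = "numeric", cellSize = "numeric",
                 nCols = "integer", nRows = "integer", mask = "matrix"))

setValidity("GridSpec", function(object) {
  if (object@cellSize <= 0) return("cellSize must be > 0")
  if (object@nCols < 1L || object@nRows < 1L) return("grid must have >= 1 cell")
  if (!is.logical(object@mask)) return("mask must be logical")
  if (!all(dim(object@mask) == c(object@nRows, object@nCols)))
    return("mask must be nRows x nCols")
  TRUE
})

#' @describeIn GridSpec grid origin `c(x, y)` in metres
#' @param x a `GridSpec`
#' @export
setMethod("gridOrigin", "GridSpec", function(x) c(x = x@originX, y = x@originY))

#' @describeIn GridSpec cell edge length in metres
#' @export
setMethod("cellSize", "GridSpec", function(x) x@cellSize)

#' @describeIn GridSpec `c(nRows, nCols)`
#' @export
setMethod("gridDim", "GridSpec", function(x) c(nRows = x@nRows, nCols = x@nCols))

#' @describeIn GridSpec logical in-paddock mask (rows = northing index)
#' @export
setMethod("gridMask", "GridSpec", function(x) x@mask)

#' @describeIn GridSpec matrix of cell-centre coordinates, one row per cell id
#' @export
setMethod("cellCenters", "GridSpec", function(x) {
  s <- x@cellSize
  cols <- rep(seq_len(x@nCols), times = x@nRows)
  rows <- rep(seq_len(x@nRows), each = x@nCols)
  cbind(easting  = x@originX + (cols - 0.5) * s,
        northing = x@originY + (rows - 0.5) * s)
})

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %d x %d cells of %g m, origin (%.1f, %.1f), %d in-paddock cells\n",
              object@nRows, object@nCols, object@cellSize,
              object@originX, object@originY, sum(object@mask)))
})

#' Single-band paddock raster
#'
#' A values matrix on the same row/column convention as [GridSpec-class]
#' (rows = northing from the south, columns = easting from the west).
#' `NA` marks nodata / out-of-paddock cells. Used for elevation, NDVI and
#' aspect surfaces.
#'
#' @slot originX,originY south-west corner, metres.
#' @slot cellSize cell edge, metres.
#' @slot values numeric nRows x nCols matrix.
#' @export
setClass("PaddockRaster",
  representation(originX = "numeric", originY = "numeric", cellSize = "numeric",
                 values = "matrix"))

setValidity("PaddockRaster", function(object) {
  if (object@cellSize <= 0) return("cellSize must be > 0")
  if (!is.numeric(object@values)) return("values must be numeric")
  if (nrow(object@values) < 1L || ncol(object@values) < 1L)
    return("values must be a non-empty matrix")
  TRUE
})

#' Construct a paddock raster
#'
#' @param values numeric matrix (rows = northing index from the south edge).
#' @param originX,originY south-west corner in metres.
#' @param cellSize cell edge in metres.
#' @return A [PaddockRaster-class].
#' @export
PaddockRaster <- function(values, originX = 0, originY = 0, cellSize = 5) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  new("PaddockRaster", originX = as.numeric(originX), originY = as.numeric(originY),
      cellSize = as.numeric(cellSize), values = values)
}

#' @describeIn PaddockRaster origin `c(x, y)`
#' @param x a `PaddockRaster`
#' @export
setMethod("gridOrigin", "PaddockRaster", function(x) c(x = x@originX, y = x@originY))

#' @describeIn PaddockRaster cell edge in metres
#' @export
setMethod("cellSize", "PaddockRaster", function(x) x@cellSize)

#' @describeIn PaddockRaster `c(nRows, nCols)`
#' @export
setMethod("gridDim", "PaddockRaster",
          function(x) c(nRows = nrow(x@values), nCols = ncol(x@values)))

#' @describeIn PaddockRaster the values matrix
#' @export
setMethod("rasterValues", "PaddockRaster", function(x) x@values)

setMethod("show", "PaddockRaster", function(object) {
  v <- object@values
  cat(sprintf("PaddockRaster: %d x %d cells of %g m, origin (%.1f, %.1f), range [%.4g, %.4g], %d NA\n",
              nrow(v), ncol(v), object@cellSize, object@originX, object@originY,
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)), sum(is.na(v))))
})

#' Paddock landscape feature bundle
#'
#' Everything the covariate table needs about a paddock: the boundary, tree
#' and water-trough points, fence polylines, and elevation and NDVI rasters,
#' all in one projected coordinate system (metres).
#'
#' @slot boundary a [PaddockBoundary-class].
#' @slot trees,troughs numeric n x 2 matrices of point coordinates.
#' @slot fences list of numeric n x 2 matrices (polylines). Defaults to the
#'   boundary ring when no separate fence layer exists.
#' @slot elevation,ndvi [PaddockRaster-class] surfaces.
#' @export
setClass("LandscapeFeatures",
  representation(boundary = "PaddockBoundary", trees = "matrix",
                 troughs = "matrix", fences = "list",
                 elevation = "PaddockRaster", ndvi = "PaddockRaster"))

setValidity("LandscapeFeatures", function(object) {
  for (nm in c("trees", "troughs")) {
    m <- slot(object, nm)
    if (nrow(m) > 0L && (ncol(m) != 2L || !all(is.finite(m))))
      return(sprintf("%s must be a finite n x 2 matrix", nm))
  }
  if (!all(vapply(object@fences, function(f) is.matrix(f) && ncol(f) == 2L, logical(1L))))
    return("fences must be a list of n x 2 matrices")
  TRUE
})

#' Construct a landscape feature bundle
#'
#' @param boundary a [PaddockBoundary-class].
#' @param trees,troughs n x 2 coordinate matrices (may be empty).
#' @param fences list of polyline matrices; `NULL` uses the boundary ring
#'   (a fully fenced paddock).
#' @param elevation,ndvi [PaddockRaster-class] surfaces.
#' @return A [LandscapeFeatures-class].
#' @export
LandscapeFeatures <- function(boundary, trees, troughs, fences = NULL,
                              elevation, ndvi) {
  asXY <- function(m) {
    m <- as.matrix(m); storage.mode(m) <- "double"
    if (nrow(m)) colnames(m) <- c("easting", "northing")
    m
  }
  if (is.null(fences)) fences <- list(boundaryRing(boundary))
  new("LandscapeFeatures", boundary = boundary, trees = asXY(trees),
      troughs = asXY(troughs), fences = lapply(fences, asXY),
      elevation = elevation, ndvi = ndvi)
}

setMethod("show", "LandscapeFeatures", function(object) {
  cat(sprintf("LandscapeFeatures '%s': %d trees, %d troughs, %d fence lines, %.2f ha\n",
              object@boundary@name, nrow(object@trees), nrow(object@troughs),
              length(object@fences), paddockArea(object@boundary) / 1e4))
})

#' Livestock Residency Index grid
#'
#' Per-cell, per-hour counts of GPS fixes and the normalised Livestock
#' Residency Index (LRI): the fraction of that hour's fixes (at the given
#' level, animal or treatment) falling in each 5 m cell. Hours without any
#' fix have an undefined (NA) LRI, never zero. The aggregate map is the mean
#' of hourly LRI over defined hours.
#'
#' @slot spec the [GridSpec-class] the index is computed on.
#' @slot counts numeric nCells x nHours matrix of raw fix counts.
#' @slot lri numeric nCells x nHours matrix; each defined column sums to 1.
#' @slot hours integer vector of hour indices (columns).
#' @slot hourTotals numeric vector of per-hour fix totals.
#' @slot aggregate numeric nCells vector, mean hourly LRI.
#' @slot level `"treatment"` or `"animal"`.
#' @slot animalId animal label for animal-level grids, `NA` otherwise.
#' @slot normalized whether `lri` holds hourly proportions (TRUE) or raw
#'   hourly counts.
#' @seealso [computeLRI()], [lriAtFix()], [exportResidency()]
#' @export
setClass("ResidencyGrid",
  representation(spec = "GridSpec", counts = "matrix", lri = "matrix",
                 hours = "integer", hourTotals = "numeric",
                 aggregate = "numeric", level = "character",
                 animalId = "character", normalized = "logical"))

setValidity("ResidencyGrid", function(object) {
  nCells <- prod(gridDim(object@spec))
  if (nrow(object@counts) != nCells) return("counts rows must equal nCells")
  if (!all(dim(object@counts) == dim(object@lri))) return("counts/lri dims differ")
  if (ncol(object@counts) != length(object@hours)) return("hours length mismatch")
  if (length(object@hourTotals) != length(object@hours)) return("hourTotals length mismatch")
  if (!object@level %in% c("treatment", "animal")) return("level must be treatment/animal")
  if (any(object@counts < 0)) return("counts must be >= 0")
  ok <- object@hourTotals > 0
  if (isTRUE(object@normalized) && any(ok)) {
    s <- colSums(object@lri[, ok, drop = FALSE])
    if (any(abs(s - 1) > 1e-9)) return("defined hourly LRI columns must sum to 1")
  }
  TRUE
})

#' @describeIn ResidencyGrid the underlying [GridSpec-class]
#' @param x a `ResidencyGrid`
#' @export
setMethod("gridSpec", "ResidencyGrid", function(x) x@spec)

#' @describeIn ResidencyGrid nCells x nHours LRI matrix
#' @export
setMethod("lriValues", "ResidencyGrid", function(x) x@lri)

#' @describeIn ResidencyGrid nCells x nHours raw count matrix
#' @export
setMethod("lriCounts", "ResidencyGrid", function(x) x@counts)

#' @describeIn ResidencyGrid per-cell mean hourly LRI
#' @export
setMethod("aggregateLRI", "ResidencyGrid", function(x) x@aggregate)

#' @describeIn ResidencyGrid `"treatment"` or `"animal"`
#' @export
setMethod("residencyLevel", "ResidencyGrid", function(x) x@level)

setMethod("show", "ResidencyGrid", function(object) {
  def <- sum(object@hourTotals > 0)
  cat(sprintf("ResidencyGrid (%s%s): %d cells x %d hours (%d with fixes), %d fixes total\n",
              object@level,
              if (!is.na(object@animalId)) paste0(" ", object@animalId) else "",
              nrow(object@counts), length(object@hours), def, sum(object@counts)))
})

#' Fitted residency driver model
#'
#' A regression random forest of the Livestock Residency Index on the
#' 12-predictor covariate table, with out-of-bag (OOB) performance and
#' permutation importance. OOB residuals come from trees whose bootstrap
#' sample excluded the row, the internal ~2:1 calibration/validation split
#' of bagging.
#'
#' @slot model the underlying `ranger` fit.
#' @slot trial,treatment,hoursMode model identity labels (e.g. "T1", "IP",
#'   "AH"/"GH").
#' @slot predictors character vector of predictor columns.
#' @slot animalLevels levels of the animal factor, in integer-code order.
#' @slot oobR2,oobMSE out-of-bag performance.
#' @slot importance data.frame: predictor, importance, rank, pValue.
#' @slot nCalibration,nValidation bagging-average calibration/validation
#'   row counts (they sum to the rows fitted).
#' @slot seed,nTrees,mtry fitting parameters.
#' @export
setClass("DriverFit",
  representation(model = "ANY", trial = "character", treatment = "character",
                 hoursMode = "character", predictors = "character",
                 animalLevels = "character", oobR2 = "numeric",
                 oobMSE = "numeric", importance = "data.frame",
                 nCalibration = "integer", nValidation = "integer",
                 seed = "integer", nTrees = "integer", mtry = "integer"))

#' @describeIn DriverFit out-of-bag R-squared
#' @param x a `DriverFit`
#' @export
setMethod("oobR2", "DriverFit", function(x) x@oobR2)

#' @describeIn DriverFit out-of-bag mean squared error
#' @export
setMethod("oobMSE", "DriverFit", function(x) x@oobMSE)

#' @describeIn DriverFit importance table (predictor, importance, rank, pValue)
#' @export
setMethod("importanceTable", "DriverFit", function(x) x@importance)

setMethod("show", "DriverFit", function(object) {
  top <- object@importance$predictor[order(object@importance$rank)][1:3]
  cat(sprintf("DriverFit %s %s %s: %d trees, mtry %d, n = %d (cal %d / val %d)\n",
              object@trial, object@treatment, object@hoursMode, object@nTrees,
              object@mtry, object@nCalibration + object@nValidation,
              object@nCalibration, object@nValidation))
  cat(sprintf("  OOB R2 = %.4f, OOB MSE = %.3g; top predictors: %s\n",
              object@oobR2, object@oobMSE, paste(top, collapse = ", ")))
})
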