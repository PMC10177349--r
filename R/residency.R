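# Paddock grid construction and the Livestock Residency Index.

#' Build the paddock analysis grid
#'
#' Lays a regular grid of square cells (default 5 m) over a paddock. The
#' origin is snapped down to a multiple of the cell size, cells are
#' half-open `[x, x + s) x [y, y + s)`, and the mask marks every cell whose
#' square intersects the paddock polygon (touching counts). The same grid
#' geometry carries the interpolated NDVI map and the residency index.
#'
#' @param boundary a [PaddockBoundary-class].
#' @param cellSize cell edge in metres (default 5).
#' @return A [GridSpec-class].
#' @examples
#' b <- PaddockBoundary(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)))
#' buildGrid(b)          # 2 x 2 cells, all masked in
#' @export
buildGrid <- function(boundary, cellSize = 5) {
  stopifnot(is(boundary, "PaddockBoundary"), cellSize > 0)
  ring <- boundaryRing(boundary)
  ox <- floor(min(ring[, 1L]) / cellSize) * cellSize
  oy <- floor(min(ring[, 2L]) / cellSize) * cellSize
  nCols <- max(1L, as.integer(ceiling((max(ring[, 1L]) - ox) / cellSize)))
  nRows <- max(1L, as.integer(ceiling((max(ring[, 2L]) - oy) / cellSize)))
  mask <- matrix(FALSE, nRows, nCols)
  # cells with any corner inside (or on) the polygon
  xs <- ox + (0:nCols) * cellSize
  ys <- oy + (0:nRows) * cellSize
  nodes <- pracma::inpolygon(rep(xs, times = nRows + 1L), rep(ys, each = nCols + 1L),
                             ring[, 1L], ring[, 2L], boundary = TRUE)
  nodeIn <- matrix(nodes, nrow = nRows + 1L, ncol = nCols + 1L, byrow = TRUE)
  cornerHit <- nodeIn[1:nRows, 1:nCols] | nodeIn[1:nRows, 2:(nCols + 1L)] |
               nodeIn[2:(nRows + 1L), 1:nCols] | nodeIn[2:(nRows + 1L), 2:(nCols + 1L)]
  mask <- mask | cornerHit
  # cells crossed by a boundary edge (covers slivers and contained vertices)
  for (k in seq_len(nrow(ring) - 1L)) {
    hit <- .cellsOnSegment(ring[k, 1L], ring[k, 2L], ring[k + 1L, 1L], ring[k + 1L, 2L],
                           ox, oy, cellSize, nCols, nRows)
    mask[hit[, c("row", "col"), drop = FALSE]] <- TRUE
  }
  new("GridSpec", originX = ox, originY = oy, cellSize = cellSize,
      nCols = nCols, nRows = nRows, mask = mask)
}

#' Locate fixes on the grid
#'
#' Maps positions to grid cells under the half-open convention
#' `col = floor((easting - originX)/s) + 1`; positions exactly on the max
#' edge of the grid extent go to the last cell. Positions outside the
#' extent are an error (impossible after cleaning).
#'
#' @param points a fix table (columns `easting`, `northing`) or an n x 2
#'   coordinate matrix.
#' @param spec a [GridSpec-class].
#' @return data.frame with `col`, `row` (1-based) and the row-major `cell`
#'   id `(row - 1) * nCols + col`.
#' @export
fixToCell <- function(points, spec) {
  stopifnot(is(spec, "GridSpec"))
  if (is.data.frame(points)) points <- cbind(points$easting, points$northing)
  if (is.null(dim(points))) points <- matrix(points, ncol = 2L)
  s <- cellSize(spec); o <- gridOrigin(spec)
  col <- floor((points[, 1L] - o[["x"]]) / s) + 1
  row <- floor((points[, 2L] - o[["y"]]) / s) + 1
  col[points[, 1L] == o[["x"]] + spec@nCols * s] <- spec@nCols
  row[points[, 2L] == o[["y"]] + spec@nRows * s] <- spec@nRows
  bad <- col < 1 | col > spec@nCols | row < 1 | row > spec@nRows
  if (any(bad)) stop(sprintf("%d fix(es) outside the grid extent", sum(bad)))
  col <- as.integer(col); row <- as.integer(row)
  data.frame(col = col, row = row, cell = (row - 1L) * spec@nCols + col)
}

#' Compute the Livestock Residency Index
#'
#' Counts retained fixes per (cell, hour) and normalises each hour's counts
#' by that hour's total, so the hourly LRI of a cell is the fraction of the
#' level's fixes spent there and every defined hour sums to 1 over cells.
#' Hours with no fixes are undefined (NA), never zero. The aggregate map is
#' the mean hourly LRI over defined hours (each hour weighted equally,
#' regardless of fix dropout); raw counts are kept alongside.
#'
#' @param fixes cleaned fix table with an `hour` column ([assignHours()]).
#' @param spec a [GridSpec-class].
#' @param level `"treatment"` (all animals pooled; the model target) or
#'   `"animal"` (a single animal's index).
#' @param animal animal id, required when `level = "animal"`.
#' @param normalize `FALSE` keeps the LRI as raw hourly counts instead of
#'   hourly proportions (both conventions are in field use).
#' @return A [ResidencyGrid-class].
#' @export
computeLRI <- function(fixes, spec, level = c("treatment", "animal"),
                       animal = NULL, normalize = TRUE) {
  level <- match.arg(level)
  stopifnot(is.data.frame(fixes), "hour" %in% names(fixes))
  if (level == "animal") {
    if (is.null(animal)) stop("animal-level LRI needs an animal id")
    fixes <- fixes[fixes$animal_id == animal, , drop = FALSE]
  }
  nCells <- prod(gridDim(spec))
  nHours <- if (nrow(fixes)) max(fixes$hour) else 0L
  hours <- seq_len(nHours)
  counts <- matrix(0, nCells, nHours)
  if (nrow(fixes)) {
    cell <- fixToCell(fixes, spec)$cell
    idx <- cell + (fixes$hour - 1L) * nCells
    tab <- tabulate(idx, nbins = nCells * nHours)
    counts <- matrix(tab, nCells, nHours)
  }
  hourTotals <- colSums(counts)
  lri <- counts
  def <- hourTotals > 0
  if (normalize) {
    lri[, def] <- sweep(counts[, def, drop = FALSE], 2L, hourTotals[def], "/")
  }
  lri[, !def] <- NA_real_
  aggregate <- if (any(def)) rowMeans(lri[, def, drop = FALSE]) else rep(NA_real_, nCells)
  new("ResidencyGrid", spec = spec, counts = counts, lri = lri,
      hours = as.integer(hours), hourTotals = hourTotals, aggregate = aggregate,
      level = level, normalized = normalize,
      animalId = if (level == "animal") as.character(animal) else NA_character_)
}

#' Look up the residency target at each fix
#'
#' Returns, for every fix, the LRI of the grid cell containing it during
#' the fix's hour — the per-row model target. Fixes in hours with an
#' undefined LRI yield `NA` (such rows are later excluded, with a count,
#' by the table assembler).
#'
#' @param fixes fix table with `hour`.
#' @param residency a [ResidencyGrid-class] (treatment level for the model
#'   target).
#' @return Numeric vector, one LRI value per fix.
#' @export
lriAtFix <- function(fixes, residency) {
  stopifnot(is(residency, "ResidencyGrid"), "hour" %in% names(fixes))
  cell <- fixToCell(fixes, gridSpec(residency))$cell
  out <- rep(NA_real_, nrow(fixes))
  known <- fixes$hour %in% residency@hours
  out[known] <- residency@lri[cbind(cell[known], fixes$hour[known])]
  out
}

#' Export a residency grid
#'
#' Writes the aggregate LRI map as an ESRI ASCII raster (cells outside the
#' paddock mask as nodata) and the full per-cell-per-hour table as tidy
#' CSV (`cell_id, col, row, hour, count, lri`).
#'
#' @param residency a [ResidencyGrid-class].
#' @param prefix output path prefix; writes `<prefix>_aggregate.asc` and
#'   `<prefix>_lri.csv`.
#' @return Invisibly, the two paths.
#' @export
exportResidency <- function(residency, prefix) {
  spec <- gridSpec(residency)
  d <- gridDim(spec)
  agg <- residency@aggregate
  agg[!as.vector(t(gridMask(spec)))] <- NA_real_
  m <- matrix(agg, nrow = d[["nRows"]], ncol = d[["nCols"]], byrow = TRUE)
  ras <- PaddockRaster(m, gridOrigin(spec)[["x"]], gridOrigin(spec)[["y"]],
                       cellSize(spec))
  ascPath <- paste0(prefix, "_aggregate.asc")
  writeAsciiGrid(ras, ascPath)
  nCells <- prod(d)
  cellId <- seq_len(nCells)
  tab <- data.frame(cell_id = rep(cellId, times = length(residency@hours)),
                    col = rep(((cellId - 1L) %% d[["nCols"]]) + 1L,
                              times = length(residency@hours)),
                    row = rep(((cellId - 1L) %/% d[["nCols"]]) + 1L,
                              times = length(residency@hours)),
                    hour = rep(residency@hours, each = nCells),
                    count = as.vector(residency@counts),
                    lri = as.vector(residency@lri))
  csvPath <- paste0(prefix, "_lri.csv")
  utils::write.csv(tab, csvPath, row.names = FALSE)
  invisible(c(raster = ascPath, table = csvPath))
}
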