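# Weather joining, sheep chill index, collinearity screening, and assembly
# of the 12-predictor model table.

#' The 12 model predictors
#'
#' Column names of the driver-model predictor set, in canonical order:
#' animal (A), eastings (EA), northings (NO), near distance to trees (NT),
#' water troughs (NW) and fences (NF), NDVI, aspect (AS, degrees), elevation
#' (EL, m ASL), temperature (T, degrees C), rainfall (R, mm/h) and the sheep
#' chill index (WC).
#'
#' @return Character vector of length 12.
#' @export
modelPredictors <- function() {
  c("A", "EA", "NO", "NT", "NW", "NF", "NDVI", "AS", "EL", "T", "R", "WC")
}

#' Sheep chill index
#'
#' Combined cold-stress index for sheep (kJ m^-2 h^-1 scale) from air
#' temperature, wind speed and rainfall:
#' `C = (11.7 + 3.1 * sqrt(v)) * (40 - T) + 481 + 418 * (1 - exp(-0.04 * R))`.
#' It falls with temperature rising toward 40 degrees C, and grows with wind
#' and rain. Other chill formulations can be substituted via `formula`.
#'
#' @param temp air temperature, degrees C.
#' @param wind wind speed, m/s (>= 0).
#' @param rain rainfall, mm/h (>= 0).
#' @param formula optional replacement `function(temp, wind, rain)`.
#' @return Numeric chill index values.
#' @examples
#' windChill(40, 0, 0)   # 481: the temperature and rain terms vanish
#' @export
windChill <- function(temp, wind, rain, formula = NULL) {
  if (!all(is.finite(temp), is.finite(wind), is.finite(rain)))
    stop("chill inputs must be finite")
  if (any(wind < 0) || any(rain < 0)) stop("wind and rain must be >= 0")
  if (!is.null(formula)) return(formula(temp, wind, rain))
  (11.7 + 3.1 * sqrt(wind)) * (40 - temp) + 481 + 418 * (1 - exp(-0.04 * rain))
}

#' Join hourly weather onto fix rows
#'
#' Matches each row to the hourly weather record whose hour contains its
#' timestamp (floor-to-hour join, the resolution of an airport station
#' series) and appends temperature `T`, rainfall `R` and the chill index
#' `WC` computed from temperature, wind and rain.
#'
#' @param rows data.frame with a POSIXct `timestamp` column.
#' @param weather data.frame: `timestamp` (POSIXct, on the hour), `temp_c`,
#'   `rain_mm`, `wind_ms`.
#' @param chillFormula optional chill replacement, see [windChill()].
#' @return `rows` with `T`, `R`, `WC` columns appended.
#' @export
joinWeather <- function(rows, weather, chillFormula = NULL) {
  stopifnot(is.data.frame(rows), is.data.frame(weather),
            all(c("timestamp", "temp_c", "rain_mm", "wind_ms") %in% names(weather)))
  rowHour <- floor(as.numeric(rows$timestamp) / 3600)
  wxHour <- floor(as.numeric(weather$timestamp) / 3600)
  m <- match(rowHour, wxHour)
  if (anyNA(m)) {
    gaps <- sort(unique(rowHour[is.na(m)]))
    stop("weather series does not cover hour(s): ",
         paste(format(as.POSIXct(gaps * 3600, origin = "1970-01-01", tz = "UTC")),
               collapse = ", "))
  }
  rows$T <- weather$temp_c[m]
  rows$R <- weather$rain_mm[m]
  rows$WC <- windChill(rows$T, weather$wind_ms[m], rows$R, formula = chillFormula)
  rows
}

#' Iterative variance-inflation-factor screen
#'
#' Computes `VIF_j = 1 / (1 - R^2_j)` for each numeric column from an
#' ordinary regression of that column on all the others, then repeatedly
#' drops the largest-VIF column while the maximum exceeds `threshold`
#' (ties broken deterministically by column-name order). A perfectly
#' collinear column has unbounded VIF and falls first; a constant column
#' is an error.
#'
#' @param table data.frame of numeric predictor columns (>= 2 columns,
#'   more rows than columns).
#' @param threshold VIF threshold (default 5).
#' @return List: `retained` (column names), `vif` (named VIFs of the
#'   retained set), `dropped` (in removal order), `trace` (max VIF at each
#'   removal).
#' @export
vifFilter <- function(table, threshold = 5) {
  table <- as.data.frame(table)
  stopifnot(ncol(table) >= 2L, nrow(table) > ncol(table))
  if (!all(vapply(table, is.numeric, logical(1L)))) stop("all columns must be numeric")
  if (any(vapply(table, function(x) stats::var(x) == 0, logical(1L))))
    stop("constant column(s) present; remove before VIF screening")
  cols <- sort(names(table))                 # name order fixes tie-breaks
  dropped <- character(0); trace <- numeric(0)
  repeat {
    vifs <- vapply(cols, function(j) {
      # perfect fits (exact collinearity) are expected here: VIF becomes Inf
      r2 <- suppressWarnings(
        summary(stats::lm(stats::reformulate(cols[cols != j], response = j),
                          data = table))$r.squared)
      1 / (1 - r2)
    }, numeric(1L))
    if (max(vifs) <= threshold || length(cols) == 2L) break
    worst <- cols[which.max(vifs)]           # which.max: first of tied names
    dropped <- c(dropped, worst)
    trace <- c(trace, max(vifs))
    cols <- setdiff(cols, worst)
  }
  list(retained = cols, vif = vifs, dropped = dropped, trace = trace)
}

#' Assemble the 12-predictor model table
#'
#' Builds one row per retained fix: animal id and coordinates from the fix;
#' near distances to trees, troughs and fences; elevation, aspect and NDVI
#' sampled at the fix; temperature, rainfall and chill index joined by
#' hour; and the treatment-level LRI of the fix's cell-hour as the target.
#' Rows missing any covariate (nodata NDVI cell, flat-aspect cell,
#' undefined LRI hour, ...) are dropped with a per-cause count in the
#' `dropReport` attribute.
#'
#' @param fixes cleaned fix table with `hour` ([cleanFixes()],
#'   [assignHours()]).
#' @param residency treatment-level [ResidencyGrid-class].
#' @param landscape a [LandscapeFeatures-class].
#' @param weather hourly weather data.frame (see [joinWeather()]).
#' @param aspect optional precomputed aspect [PaddockRaster-class]
#'   (computed from the landscape elevation if `NULL`).
#' @param chillFormula optional chill replacement, see [windChill()].
#' @return data.frame with `timestamp`, `hour`, the 12 predictor columns of
#'   [modelPredictors()] and the `LRI` target; attribute `dropReport`
#'   counts dropped rows by cause.
#' @export
assembleModelTable <- function(fixes, residency, landscape, weather,
                               aspect = NULL, chillFormula = NULL) {
  stopifnot(is(residency, "ResidencyGrid"), is(landscape, "LandscapeFeatures"))
  if (residency@level != "treatment")
    stop("the model target uses the treatment-level residency grid")
  if (is.null(aspect)) aspect <- computeAspect(landscape@elevation)
  pts <- cbind(fixes$easting, fixes$northing)
  tab <- data.frame(timestamp = fixes$timestamp, hour = fixes$hour,
                    A = fixes$animal_id, EA = fixes$easting, NO = fixes$northing,
                    stringsAsFactors = FALSE)
  tab$NT <- if (nrow(landscape@trees)) nearDistance(pts, landscape@trees) else NA_real_
  tab$NW <- if (nrow(landscape@troughs)) nearDistance(pts, landscape@troughs) else NA_real_
  tab$NF <- nearDistance(pts, landscape@fences)
  tab$NDVI <- sampleRaster(pts, landscape@ndvi)
  tab$AS <- sampleRaster(pts, aspect)
  tab$EL <- sampleRaster(pts, landscape@elevation)
  tab <- joinWeather(tab, weather, chillFormula = chillFormula)
  tab$LRI <- lriAtFix(fixes, residency)
  causes <- c(NT = "missingNT", NW = "missingNW", NF = "missingNF",
              NDVI = "missingNDVI", AS = "flatOrMissingAspect",
              EL = "missingElevation", LRI = "undefinedLRI")
  bad <- rep(FALSE, nrow(tab))
  report <- list(nInput = nrow(tab))
  for (col in names(causes)) {
    this <- is.na(tab[[col]]) & !bad
    report[[causes[[col]]]] <- sum(this)
    bad <- bad | this
  }
  report$nRetained <- sum(!bad)
  out <- tab[!bad, c("timestamp", "hour", modelPredictors(), "LRI"), drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropReport") <- report
  out
}
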