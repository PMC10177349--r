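# Reading, validating and cleaning GPS collar fix tables.
#
# A fix table is a data.frame with one row per fix:
#   animal_id  character
#   timestamp  POSIXct (timezone-aware)
#   easting    m (projected)
#   northing   m (projected)
#   ttf        s, time-to-fix (GPS quality proxy)
# plus an integer `hour` column after assignHours(). Rows are ordered by
# (animal_id, timestamp).

#' Burst fix schedule
#'
#' Describes the collar duty cycle: fixes logged at `burstOffsets` seconds
#' within a burst, then a sleep. The default is the 5-fixes-per-minute
#' schedule (0, 15, 30, 45, 60 s) followed by 4 min of sleep, i.e. one
#' 5-minute cycle and 60 fixes per animal-hour.
#'
#' @param burstOffsets nondecreasing offsets within a burst, seconds.
#' @param sleep sleep duration after the burst, seconds (> 0).
#' @return A list with class `FixSchedule`.
#' @export
fixSchedule <- function(burstOffsets = c(0, 15, 30, 45, 60), sleep = 240) {
  stopifnot(!is.unsorted(burstOffsets), sleep > 0)
  structure(list(burstOffsets = as.numeric(burstOffsets), sleep = as.numeric(sleep),
                 cycle = max(burstOffsets) + sleep),
            class = "FixSchedule")
}

#' @export
print.FixSchedule <- function(x, ...) {
  cat(sprintf("FixSchedule: fixes at %s s, sleep %g s (%g-s cycle, %g fixes/h)\n",
              paste(x$burstOffsets, collapse = ", "), x$sleep, x$cycle,
              3600 / x$cycle * length(x$burstOffsets)))
  invisible(x)
}

#' Read a GPS fix table
#'
#' Reads a delimited fix file, remaps columns, parses timestamps, and
#' returns a time-sorted fix table. Malformed rows (unparseable timestamp,
#' non-finite coordinates, negative time-to-fix) are rejected and counted,
#' not fixed up.
#'
#' @param path CSV file with the fix columns.
#' @param schema named character vector mapping the canonical names
#'   `animal_id`, `timestamp`, `easting`, `northing`, `ttf` to the file's
#'   column names.
#' @param tz timezone for timestamp parsing (default UTC).
#' @return Fix table data.frame sorted by animal then time, with a
#'   `readReport` attribute counting rejected rows; an empty file yields a
#'   zero-row table with a warning.
#' @export
readFixes <- function(path,
                      schema = c(animal_id = "animal_id", timestamp = "timestamp",
                                 easting = "easting_m", northing = "northing_m",
                                 ttf = "ttf_s"),
                      tz = "UTC") {
  stopifnot(file.exists(path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(unname(schema), names(raw))
  if (length(missing))
    stop("fix file lacks required column(s): ", paste(missing, collapse = ", "))
  fx <- data.frame(animal_id = as.character(raw[[schema[["animal_id"]]]]),
                   timestamp = .parseTimestamp(raw[[schema[["timestamp"]]]], tz),
                   easting   = suppressWarnings(as.numeric(raw[[schema[["easting"]]]])),
                   northing  = suppressWarnings(as.numeric(raw[[schema[["northing"]]]])),
                   ttf       = suppressWarnings(as.numeric(raw[[schema[["ttf"]]]])),
                   stringsAsFactors = FALSE)
  badTime  <- is.na(fx$timestamp)
  badCoord <- !is.finite(fx$easting) | !is.finite(fx$northing)
  badTtf   <- !is.finite(fx$ttf) | fx$ttf < 0
  bad <- badTime | badCoord | badTtf
  report <- list(nRows = nrow(fx), nBadTimestamp = sum(badTime),
                 nBadCoordinate = sum(badCoord & !badTime),
                 nBadTtf = sum(badTtf & !badTime & !badCoord),
                 nRead = sum(!bad))
  if (any(bad))
    warning(sprintf("rejected %d malformed row(s) of %d", sum(bad), nrow(fx)))
  if (nrow(fx) == 0L) warning("empty fix file: ", path)
  fx <- fx[!bad, , drop = FALSE]
  fx <- fx[order(fx$animal_id, fx$timestamp), , drop = FALSE]
  rownames(fx) <- NULL
  attr(fx, "readReport") <- report
  fx
}

.parseTimestamp <- function(x, tz) {
  if (inherits(x, "POSIXct")) return(x)
  x <- as.character(x)
  out <- as.POSIXct(x, tz = tz, format = "%Y-%m-%dT%H:%M:%OS")
  miss <- is.na(out) & !is.na(x)
  if (any(miss))
    out[miss] <- as.POSIXct(x[miss], tz = tz, format = "%Y-%m-%d %H:%M:%OS")
  out                                        # still-NA rows are counted malformed
}

#' Clean a fix table
#'
#' Applies the standard collar QC rules in order: (1) drop fixes whose
#' time-to-fix exceeded `maxTTF` seconds (strictly longer; a fix of exactly
#' `maxTTF` s is kept), (2) drop fixes outside the paddock boundary (points
#' on the fence line are kept), (3) drop duplicated (animal, timestamp)
#' rows, keeping the first. Each removed fix is counted under the first
#' rule it violated, so the per-rule counts plus the retained count equal
#' the input count exactly.
#'
#' @param fixes fix table (see [readFixes()]).
#' @param boundary a [PaddockBoundary-class].
#' @param maxTTF time-to-fix threshold in seconds (default 16).
#' @return The retained fix table, in the input order, with a `cleanReport`
#'   attribute (see [cleanReport()]). Removing everything returns an empty
#'   table with a warning, not an error.
#' @examples
#' b <- PaddockBoundary(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)))
#' fx <- data.frame(animal_id = "a", timestamp = as.POSIXct(1:3, tz = "UTC"),
#'                  easting = c(5, 50, 5), northing = c(5, 5, 5), ttf = c(4, 4, 17))
#' cleanReport(cleanFixes(fx, b))
#' @export
cleanFixes <- function(fixes, boundary, maxTTF = 16) {
  stopifnot(is.data.frame(fixes), is(boundary, "PaddockBoundary"), maxTTF >= 0)
  n <- nrow(fixes)
  if (n == 0L) {
    out <- fixes
    attr(out, "cleanReport") <- list(nInput = 0L, nRemovedTTF = 0L,
                                     nRemovedOutside = 0L, nRemovedDuplicate = 0L,
                                     nRetained = 0L, maxTTF = maxTTF)
    return(out)
  }
  badTTF <- fixes$ttf > maxTTF
  outside <- !insidePaddock(fixes$easting, fixes$northing, boundary) & !badTTF
  dup <- rep(FALSE, n)                       # duplicates among rule-1/2 survivors
  surv <- !(badTTF | outside)
  dup[surv] <- duplicated(fixes[surv, c("animal_id", "timestamp"), drop = FALSE])
  keep <- !(badTTF | outside | dup)
  out <- fixes[keep, , drop = FALSE]
  rownames(out) <- NULL
  report <- list(nInput = n, nRemovedTTF = sum(badTTF),
                 nRemovedOutside = sum(outside), nRemovedDuplicate = sum(dup),
                 nRetained = sum(keep), maxTTF = maxTTF)
  if (report$nRetained == 0L)
    warning("cleaning removed every fix (", n, " input rows)")
  attr(out, "cleanReport") <- report
  out
}

#' Cleaning bookkeeping
#'
#' @param fixes a fix table returned by [cleanFixes()].
#' @return The `cleanReport` attribute: a list of input, per-rule removed,
#'   and retained counts.
#' @export
cleanReport <- function(fixes) attr(fixes, "cleanReport")

#' Assign trial hour indices
#'
#' Labels each fix with its categorical trial hour: hour 1 is the first
#' hour of recording, in half-open bins
#' `hour = 1 + floor((timestamp - trialStart) / 3600)`. Re-applying with
#' the same `trialStart` is a no-op.
#'
#' @param fixes fix table.
#' @param trialStart POSIXct start of the trial recording window.
#' @return The fix table with an integer `hour` column.
#' @export
assignHours <- function(fixes, trialStart) {
  stopifnot(is.data.frame(fixes), inherits(trialStart, "POSIXct"))
  if (nrow(fixes) == 0L) {
    fixes$hour <- integer(0)
    return(fixes)
  }
  dt <- as.numeric(difftime(fixes$timestamp, trialStart, units = "secs"))
  early <- which(dt < 0)
  if (length(early))
    stop(sprintf("fix %d (animal %s, %s) precedes trial start",
                 early[1L], fixes$animal_id[early[1L]],
                 format(fixes$timestamp[early[1L]])))
  fixes$hour <- 1L + as.integer(floor(dt / 3600))
  fixes
}
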