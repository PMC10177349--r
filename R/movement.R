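# Step distances and speeds, movement states, behaviour recoding,
# accelerometer count aggregation.

#' Euclidean step distance between two fixes
#'
#' Distance (m) between a first position (`a`, `b`) and a second position
#' (`aa`, `bb`) on projected coordinates:
#' `sqrt((aa - a)^2 + (bb - b)^2)`.
#'
#' @param a,b first easting and northing (m).
#' @param aa,bb second easting and northing (m).
#' @return Numeric vector of distances (m).
#' @examples
#' stepDistance(0, 0, 3, 4)  # 5
#' @export
stepDistance <- function(a, b, aa, bb) {
  if (!all(is.finite(a), is.finite(b), is.finite(aa), is.finite(bb)))
    stop("coordinates must be finite")
  sqrt((aa - a)^2 + (bb - b)^2)
}

#' Steps between consecutive fixes
#'
#' Builds the step table from a cleaned fix table: one row per pair of
#' consecutive fixes of the same animal, with distance, elapsed seconds and
#' speed = distance / elapsed. Steps are never formed across animals. Steps
#' spanning a cleaning gap (elapsed more than `gapFactor` times the
#' schedule's nominal spacing) are kept but flagged `gap = TRUE`, so that
#' summaries can exclude them.
#'
#' @param fixes cleaned fix table, time-sorted within animal (an `hour`
#'   column, if present, is carried over from the step's first fix).
#' @param schedule a [fixSchedule()]; its modal inter-fix spacing sets the
#'   gap flag.
#' @param gapFactor multiple of the nominal spacing beyond which a step is
#'   flagged as spanning a gap.
#' @return data.frame: animal_id, t0, t1, elapsed, distance, speed, gap
#'   (and hour).
#' @export
makeSteps <- function(fixes, schedule = fixSchedule(), gapFactor = 2) {
  stopifnot(is.data.frame(fixes))
  nominal <- min(diff(schedule$burstOffsets))
  pieces <- lapply(split(fixes, fixes$animal_id), function(tr) {
    n <- nrow(tr)
    if (n < 2L) return(NULL)
    elapsed <- as.numeric(difftime(tr$timestamp[-1L], tr$timestamp[-n], units = "secs"))
    if (any(elapsed <= 0))
      stop("non-increasing timestamps within animal ", tr$animal_id[1L])
    out <- data.frame(animal_id = tr$animal_id[-n],
                      t0 = tr$timestamp[-n], t1 = tr$timestamp[-1L],
                      elapsed = elapsed,
                      distance = stepDistance(tr$easting[-n], tr$northing[-n],
                                              tr$easting[-1L], tr$northing[-1L]),
                      stringsAsFactors = FALSE)
    out$speed <- out$distance / out$elapsed
    out$gap <- out$elapsed > gapFactor * nominal
    if (!is.null(tr$hour)) out$hour <- tr$hour[-n]
    out
  })
  out <- do.call(rbind, pieces)
  if (is.null(out))
    out <- data.frame(animal_id = character(0), t0 = as.POSIXct(character(0)),
                      t1 = as.POSIXct(character(0)), elapsed = numeric(0),
                      distance = numeric(0), speed = numeric(0), gap = logical(0))
  rownames(out) <- NULL
  out
}

#' Speed of a single step
#'
#' @param a,b,aa,bb coordinates as in [stepDistance()].
#' @param t0,t1 POSIXct (or numeric seconds) of the two fixes; `t1` must be
#'   after `t0`.
#' @return List with `distance` (m), `elapsed` (s) and `speed` (m/s).
#' @examples
#' stepSpeed(0, 0, 3, 4, 0, 5)$speed  # 1 m/s
#' @export
stepSpeed <- function(a, b, aa, bb, t0, t1) {
  elapsed <- as.numeric(t1) - as.numeric(t0)
  if (any(elapsed <= 0)) stop("elapsed time must be positive (t1 > t0)")
  d <- stepDistance(a, b, aa, bb)
  list(distance = d, elapsed = elapsed, speed = d / elapsed)
}

#' Hourly mean speed
#'
#' Mean speed per trial hour, computed the way flock-level figures are
#' drawn: first the mean speed of each animal within the hour, then the
#' mean of those animal means (so each collared animal carries equal
#' weight). Hours without steps are absent from the result; an empty hour
#' is a missing value, never zero.
#'
#' @param steps step table from [makeSteps()] with an `hour` column.
#' @param excludeGaps drop gap-flagged steps first (default TRUE).
#' @return data.frame: hour, meanSpeed (m/s), nAnimals.
#' @export
hourlyMeanSpeed <- function(steps, excludeGaps = TRUE) {
  stopifnot(is.data.frame(steps), "hour" %in% names(steps))
  if (excludeGaps && "gap" %in% names(steps)) steps <- steps[!steps$gap, , drop = FALSE]
  if (nrow(steps) == 0L)
    return(data.frame(hour = integer(0), meanSpeed = numeric(0), nAnimals = integer(0)))
  perAnimal <- stats::aggregate(speed ~ hour + animal_id, data = steps, FUN = mean)
  out <- stats::aggregate(speed ~ hour, data = perAnimal, FUN = mean)
  nA <- stats::aggregate(animal_id ~ hour, data = perAnimal,
                         FUN = function(x) length(unique(x)))
  out <- merge(out, nA, by = "hour")
  names(out) <- c("hour", "meanSpeed", "nAnimals")
  out[order(out$hour), , drop = FALSE]
}

#' Movement state from speed
#'
#' Two-state classification against the conventional sheep travelling
#' threshold: speeds strictly greater than `threshold` (default 0.15 m/s)
#' are `"fast"`, others `"slow"`.
#'
#' @param speed numeric speeds (m/s), nonnegative.
#' @param threshold m/s.
#' @return Character vector of `"slow"` / `"fast"`.
#' @examples
#' classifyMovementState(c(0.15, 0.16))  # slow, fast
#' @export
classifyMovementState <- function(speed, threshold = 0.15) {
  if (any(!is.finite(speed)) || any(speed < 0)) stop("speeds must be finite and >= 0")
  ifelse(speed > threshold, "fast", "slow")
}

.behaviorMap <- c("s" = "S", "standing" = "S",
                  "l" = "L", "lying" = "L",
                  "standing grazing" = "G", "walking grazing" = "G",
                  "standing walking grazing" = "G", "grazing" = "G",
                  "walking" = "M", "running" = "M",
                  "drinking" = NA_character_)

#' Recode raw behaviour observations
#'
#' Collapses scan-sampling behaviour codes into four classes: standing (S),
#' lying (L), grazing (G; any code involving grazing), moving (M; walking
#' or running). Drinking observations are dropped (`NA`), mirroring their
#' removal from analysis when too rare to model.
#'
#' @param rawCode character vector of raw codes (case-insensitive; hyphens
#'   and underscores treated as spaces).
#' @return Character vector over `{"S","L","G","M"}` with `NA` for dropped
#'   (drinking) observations.
#' @examples
#' recodeBehavior(c("running", "standing-walking-grazing", "drinking"))
#' @export
recodeBehavior <- function(rawCode) {
  key <- tolower(gsub("[-_]+", " ", trimws(as.character(rawCode))))
  unknown <- setdiff(unique(key), names(.behaviorMap))
  if (length(unknown))
    stop("unknown behaviour code(s): ", paste(unknown, collapse = ", "),
         "; vocabulary: ", paste(names(.behaviorMap), collapse = ", "))
  unname(.behaviorMap[key])
}

#' Hourly activity counts from leg accelerometers
#'
#' Aggregates per-minute step and lying counts: per-hour sum within each
#' animal, then the mean across animals per hour. Hours with no records
#' are simply absent (missing), never zero-filled. Overlapping minute
#' records for the same animal are an error.
#'
#' @param counts data.frame: animal_id, timestamp (POSIXct, one row per
#'   animal-minute), steps, lying.
#' @param trialStart POSIXct trial start for hour binning.
#' @return data.frame: hour, meanSteps, meanLying, nAnimals.
#' @export
hourlyActivityCounts <- function(counts, trialStart) {
  stopifnot(is.data.frame(counts),
            all(c("animal_id", "timestamp", "steps", "lying") %in% names(counts)))
  if (any(counts$steps < 0) || any(counts$lying < 0)) stop("counts must be >= 0")
  minuteKey <- paste(counts$animal_id,
                     floor(as.numeric(counts$timestamp) / 60))
  if (anyDuplicated(minuteKey)) stop("overlapping minute records for an animal")
  counts <- assignHours(counts, trialStart)
  perAnimal <- stats::aggregate(cbind(steps, lying) ~ hour + animal_id,
                                data = counts, FUN = sum)
  out <- stats::aggregate(cbind(steps, lying) ~ hour, data = perAnimal, FUN = mean)
  nA <- stats::aggregate(animal_id ~ hour, data = perAnimal,
                         FUN = function(x) length(unique(x)))
  out <- merge(out, nA, by = "hour")
  names(out) <- c("hour", "meanSteps", "meanLying", "nAnimals")
  out[order(out$hour), , drop = FALSE]
}
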