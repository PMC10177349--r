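# Seeded synthetic study generator: paddock landscapes, hourly weather, and
# flock trajectories from a biased correlated random walk over a known
# utility surface, observed through the collar burst schedule.

#' Simulation configuration
#'
#' All knobs of the synthetic study, with defaults emulating the field
#' design this package targets: a ~22.5 ha paddock, 15 collared animals,
#' six-day trials, the 5-fixes-per-minute / 4-minute-sleep collar schedule,
#' diurnal dawn/dusk grazing peaks, and residency driven by weighted,
#' standardized landscape covariates. Driver weights are per activity
#' state, over `ndvi`, `el` (elevation), `nt` (distance to trees), `nw`
#' (distance to water) and `shelter` (tree proximity, active only in hours
#' whose chill index exceeds `chillThreshold`).
#'
#' @param seed integer master seed; every downstream draw derives from it.
#' @param ... overrides of the defaults listed in the source (paddock
#'   dimensions, tree layout, elevation span, NDVI range, state speeds,
#'   heading mixture weights, observation model, weather model, ...).
#' @return A `SimConfig` (classed list).
#' @examples
#' cfg <- simConfig(seed = 7, nDays = 1, nAnimals = 5)
#' cfg$driverWeights$grazing
#' @export
simConfig <- function(seed = 1, ...) {
  zeroW <- c(ndvi = 0, el = 0, nt = 0, nw = 0, shelter = 0)
  cfg <- list(
    seed = as.integer(seed),
    paddockWidth = 500, paddockHeight = 450,      # m (~22.5 ha)
    cellSize = 5,
    nTrees = 40, treeLayout = "clustered-north",  # or "scattered", "west-row"
    troughPosition = "southwest",                 # or "northwest"
    elevRange = c(935, 984), elevNoiseAmp = 3,    # m ASL span + smooth noise
    ndviRange = c(0.1, 0.4),
    nAnimals = 15, nDays = 6,
    trialStart = as.POSIXct("2014-04-23 00:00:00", tz = "UTC"),
    driverWeights = list(resting = zeroW, grazing = zeroW, travelling = zeroW),
    chillThreshold = 750,                         # chill-index shelter switch
    grazingPeaks = list(c(6, 10), c(15, 19)),     # local hours of dawn/dusk peaks
    nightHours = c(20, 5),
    statePersistence = 0.92,
    stateSpeeds = c(resting = 0.01, grazing = 0.08, travelling = 0.3),  # m/s
    speedSDLog = 0.3,
    biasStrength = 1, headingPersistence = 0.5,
    cohesion = 0.2, directionNoise = 0.6,
    schedule = fixSchedule(),
    jitterSD = 1, pSlowFix = 0.1, dropout = 0.05,
    weather = list(tempMean = 10, tempAmp = 6, tempMaxHour = 15,
                   tempNoiseSD = 1, rainEventProb = 0.04, rainPersistence = 0.6,
                   rainMeanIntensity = 1.5, windMean = 4, windSD = 2,
                   windPersistence = 0.7))
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown SimConfig field(s): ", paste(unknown, collapse = ", "))
  for (nm in names(dots)) {
    if (nm %in% c("driverWeights", "weather") && is.list(dots[[nm]])) {
      for (sub in names(dots[[nm]])) {
        v <- dots[[nm]][[sub]]
        if (nm == "driverWeights") {
          w <- zeroW; w[names(v)] <- v
          cfg$driverWeights[[sub]] <- w
        } else cfg$weather[[sub]] <- v
      }
    } else cfg[[nm]] <- dots[[nm]]
  }
  structure(cfg, class = "SimConfig")
}

#' @export
print.SimConfig <- function(x, ...) {
  cat(sprintf("SimConfig (seed %d): %g x %g m paddock, %d animals, %d day(s)\n",
              x$seed, x$paddockWidth, x$paddockHeight, x$nAnimals, x$nDays))
  for (s in names(x$driverWeights)) {
    w <- x$driverWeights[[s]]
    if (any(w != 0))
      cat(sprintf("  %s weights: %s\n", s,
                  paste(sprintf("%s=%g", names(w)[w != 0], w[w != 0]),
                        collapse = ", ")))
  }
  invisible(x)
}

# smooth random field: sum of Gaussian bumps, returned as nRows x nCols matrix
.smoothField <- function(nRows, nCols, cellSize, nBumps = 8) {
  xc <- (seq_len(nCols) - 0.5) * cellSize
  yc <- (seq_len(nRows) - 0.5) * cellSize
  W <- nCols * cellSize; H <- nRows * cellSize
  f <- matrix(0, nRows, nCols)
  for (b in seq_len(nBumps)) {
    cx <- stats::runif(1, 0, W); cy <- stats::runif(1, 0, H)
    sx <- stats::runif(1, 0.1, 0.35) * W; sy <- stats::runif(1, 0.1, 0.35) * H
    amp <- stats::rnorm(1)
    f <- f + amp * outer(exp(-(yc - cy)^2 / (2 * sy^2)),
                         exp(-(xc - cx)^2 / (2 * sx^2)))
  }
  f
}

.rescale <- function(m, lo, hi) {
  r <- range(m)
  if (diff(r) == 0) return(matrix((lo + hi) / 2, nrow(m), ncol(m)))
  lo + (m - r[1L]) / diff(r) * (hi - lo)
}

#' Generate a synthetic paddock landscape
#'
#' Builds a rectangular paddock with seeded tree and trough layouts, a
#' south-to-north elevation trend with smooth noise, and a smooth NDVI
#' field rescaled exactly to the configured range. Tree layouts:
#' `"clustered-north"` (90% of trees in the northern third, the
#' native-paddock pattern), `"scattered"`, or `"west-row"` (a shelter row
#' along the western fence, the improved-paddock pattern). Deterministic
#' given `config$seed`.
#'
#' @param config a [simConfig()].
#' @return A [LandscapeFeatures-class].
#' @export
generateLandscape <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  W <- config$paddockWidth; H <- config$paddockHeight
  boundary <- PaddockBoundary(cbind(c(0, W, W, 0), c(0, 0, H, H)), "synthetic")
  spec <- buildGrid(boundary, config$cellSize)
  d <- gridDim(spec)
  .withSeed(config$seed + 11L, {
    n <- config$nTrees
    trees <- switch(config$treeLayout,
      "clustered-north" = {
        north <- stats::runif(n) < 0.9
        cbind(stats::runif(n, 0.02 * W, 0.98 * W),
              ifelse(north, stats::runif(n, 0.70 * H, 0.98 * H),
                            stats::runif(n, 0.02 * H, 0.66 * H)))
      },
      "scattered" = cbind(stats::runif(n, 0.02 * W, 0.98 * W),
                          stats::runif(n, 0.02 * H, 0.98 * H)),
      "west-row" = cbind(stats::runif(n, 3, 10),
                         seq(0.05 * H, 0.95 * H, length.out = n)),
      stop("unknown treeLayout: ", config$treeLayout))
    trough <- switch(config$troughPosition,
                     southwest = c(15, 15),
                     northwest = c(15, H - 15),
                     stop("unknown troughPosition: ", config$troughPosition))
    northing <- (seq_len(d[["nRows"]]) - 0.5) * config$cellSize
    trend <- config$elevRange[1L] +
      diff(config$elevRange) * matrix(northing / H, d[["nRows"]], d[["nCols"]])
    noise <- .smoothField(d[["nRows"]], d[["nCols"]], config$cellSize)
    elev <- trend + .rescale(noise, -config$elevNoiseAmp, config$elevNoiseAmp)
    ndvi <- .rescale(.smoothField(d[["nRows"]], d[["nCols"]], config$cellSize),
                     config$ndviRange[1L], config$ndviRange[2L])
    LandscapeFeatures(boundary, trees, matrix(trough, ncol = 2L),
                      fences = NULL,
                      elevation = PaddockRaster(elev, 0, 0, config$cellSize),
                      ndvi = PaddockRaster(ndvi, 0, 0, config$cellSize))
  })
}

#' Generate an hourly weather series
#'
#' Sinusoidal diurnal temperature (daily maximum at the configured hour)
#' with autocorrelated noise, sparse persistent rainfall events, and
#' autocorrelated nonnegative wind. Deterministic given `config$seed`.
#'
#' @param config a [simConfig()].
#' @return data.frame: `timestamp` (hourly POSIXct), `temp_c`, `rain_mm`,
#'   `wind_ms`.
#' @export
generateWeather <- function(config) {
  stopifnot(inherits(config, "SimConfig"), config$nDays >= 1)
  w <- config$weather
  nH <- config$nDays * 24L
  hod <- (seq_len(nH) - 1L) %% 24L
  .withSeed(config$seed + 23L, {
    ar <- function(n, sd, rho) {
      e <- stats::rnorm(n, 0, sd)
      if (sd == 0) return(numeric(n))
      stats::filter(e, rho, method = "recursive")
    }
    temp <- w$tempMean + w$tempAmp * cos(2 * pi * (hod - w$tempMaxHour) / 24) +
      as.numeric(ar(nH, w$tempNoiseSD, 0.6))
    raining <- logical(nH); rain <- numeric(nH)
    state <- FALSE
    for (h in seq_len(nH)) {
      state <- if (state) stats::runif(1) < w$rainPersistence
               else stats::runif(1) < w$rainEventProb
      raining[h] <- state
      if (state) rain[h] <- stats::rexp(1, 1 / w$rainMeanIntensity)
    }
    wind <- abs(w$windMean + as.numeric(ar(nH, w$windSD, w$windPersistence)))
    data.frame(timestamp = config$trialStart + (seq_len(nH) - 1L) * 3600,
               temp_c = temp, rain_mm = rain, wind_ms = wind)
  })
}

# central-difference gradient of a cell matrix -> list(gx, gy) per metre
.gridGradient <- function(m, cellSize) {
  nr <- nrow(m); nc <- ncol(m)
  cp <- pmin(1:nc + 1L, nc); cm <- pmax(1:nc - 1L, 1L)
  rp <- pmin(1:nr + 1L, nr); rm <- pmax(1:nr - 1L, 1L)
  gx <- sweep(m[, cp, drop = FALSE] - m[, cm, drop = FALSE], 2L,
              (cp - cm) * cellSize, "/")
  gy <- sweep(m[rp, , drop = FALSE] - m[rm, , drop = FALSE], 1L,
              (rp - rm) * cellSize, "/")
  list(gx = gx, gy = gy)
}

#' Simulate flock trajectories
#'
#' Minute-resolution biased correlated random walk for every animal. Each
#' minute an animal keeps or redraws its activity state (resting, grazing,
#' travelling) from the diurnal schedule; its heading mixes the gradient of
#' the state's utility surface `U = sum_k w_k * standardized covariate_k`
#' (shelter terms switch on when the hour's chill index exceeds the
#' threshold), its previous heading, attraction to the flock centroid, and
#' noise; its step length follows the state's speed. Positions reflect off
#' the paddock boundary, so fence-adjacent residency arises naturally.
#'
#' @param landscape a [generateLandscape()] result.
#' @param weather a [generateWeather()] series covering the simulated days.
#' @param config the same [simConfig()].
#' @return A `SimTruth` (classed list): minute positions (`x`, `y`:
#'   animals x minutes+1 matrices), integer state matrix, per-hour shelter
#'   flags, the utility surfaces per state, and the config echo.
#' @export
simulateFlock <- function(landscape, weather, config) {
  stopifnot(inherits(config, "SimConfig"))
  W <- config$paddockWidth; H <- config$paddockHeight
  if (W <= 0 || H <= 0) stop("paddock must have positive area")
  s <- config$cellSize
  elev <- rasterValues(landscape@elevation)
  ndvi <- rasterValues(landscape@ndvi)
  nr <- nrow(elev); nc <- ncol(elev)
  ctr <- cbind(rep((seq_len(nc) - 0.5) * s, times = nr),
               rep((seq_len(nr) - 0.5) * s, each = nc))
  z <- function(m) (m - mean(m)) / stats::sd(as.vector(m))
  toMat <- function(v) matrix(v, nr, nc, byrow = TRUE)
  cov <- list(
    ndvi = z(ndvi), el = z(elev),
    nt = if (nrow(landscape@trees)) z(toMat(nearDistance(ctr, landscape@trees)))
         else matrix(0, nr, nc),
    nw = if (nrow(landscape@troughs)) z(toMat(nearDistance(ctr, landscape@troughs)))
         else matrix(0, nr, nc))
  cov$shelter <- -cov$nt                      # shelter = proximity to trees
  states <- names(config$driverWeights)
  grads <- list()
  for (st in states) {
    w <- config$driverWeights[[st]]
    base <- w[["ndvi"]] * cov$ndvi + w[["el"]] * cov$el +
            w[["nt"]] * cov$nt + w[["nw"]] * cov$nw
    grads[[st]] <- list(off = .gridGradient(base, s),
                        on = .gridGradient(base + w[["shelter"]] * cov$shelter, s))
  }
  wc <- windChill(weather$temp_c, weather$wind_ms, weather$rain_mm)
  shelterOn <- wc > config$chillThreshold
  nMin <- config$nDays * 1440L
  nA <- config$nAnimals
  probState <- function(hod) {
    inPeak <- any(vapply(config$grazingPeaks,
                         function(p) hod >= p[1L] && hod < p[2L], logical(1L)))
    night <- hod >= config$nightHours[1L] || hod < config$nightHours[2L]
    if (inPeak) c(resting = 0.15, grazing = 0.75, travelling = 0.10)
    else if (night) c(resting = 0.90, grazing = 0.05, travelling = 0.05)
    else c(resting = 0.55, grazing = 0.35, travelling = 0.10)
  }
  .withSeed(config$seed + 37L, {
    X <- matrix(NA_real_, nA, nMin + 1L)
    Y <- matrix(NA_real_, nA, nMin + 1L)
    S <- matrix(NA_integer_, nA, nMin)
    X[, 1L] <- pmin(pmax(W / 2 + stats::rnorm(nA, 0, 20), 1), W - 1)
    Y[, 1L] <- pmin(pmax(H / 2 + stats::rnorm(nA, 0, 20), 1), H - 1)
    heading <- stats::runif(nA, 0, 2 * pi)
    state <- sample.int(3L, nA, replace = TRUE, prob = probState(0))
    unit <- function(dx, dy) {
      nrm <- sqrt(dx^2 + dy^2)
      ok <- nrm > 0
      cbind(ifelse(ok, dx / nrm, 0), ifelse(ok, dy / nrm, 0))
    }
    speeds <- config$stateSpeeds
    for (t in seq_len(nMin)) {
      hod <- ((t - 1L) %/% 60L) %% 24L
      hr <- (t - 1L) %/% 60L + 1L
      p <- probState(hod)
      redraw <- stats::runif(nA) >= config$statePersistence
      if (any(redraw))
        state[redraw] <- sample.int(3L, sum(redraw), replace = TRUE, prob = p)
      S[, t] <- state
      col <- pmin(pmax(floor(X[, t] / s) + 1L, 1L), nc)
      row <- pmin(pmax(floor(Y[, t] / s) + 1L, 1L), nr)
      idx <- cbind(row, col)
      variant <- if (isTRUE(shelterOn[min(hr, length(shelterOn))])) "on" else "off"
      gxv <- numeric(nA); gyv <- numeric(nA)
      for (k in seq_along(states)) {
        sel <- state == k
        if (any(sel)) {
          g <- grads[[states[k]]][[variant]]
          gxv[sel] <- g$gx[idx[sel, , drop = FALSE]]
          gyv[sel] <- g$gy[idx[sel, , drop = FALSE]]
        }
      }
      gU <- unit(gxv, gyv)
      hU <- cbind(cos(heading), sin(heading))
      cU <- unit(mean(X[, t]) - X[, t], mean(Y[, t]) - Y[, t])
      ang <- stats::runif(nA, 0, 2 * pi)
      d <- config$biasStrength * gU + config$headingPersistence * hU +
           config$cohesion * cU + config$directionNoise * cbind(cos(ang), sin(ang))
      zero <- rowSums(d^2) == 0
      if (any(zero)) d[zero, ] <- cbind(cos(ang[zero]), sin(ang[zero]))
      heading <- atan2(d[, 2L], d[, 1L])
      step <- speeds[state] * stats::rlnorm(nA, 0, config$speedSDLog) * 60
      x1 <- X[, t] + step * cos(heading)
      y1 <- Y[, t] + step * sin(heading)
      for (r in 1:3) {                         # reflect off the rectangle
        x1 <- ifelse(x1 < 0, -x1, ifelse(x1 > W, 2 * W - x1, x1))
        y1 <- ifelse(y1 < 0, -y1, ifelse(y1 > H, 2 * H - y1, y1))
      }
      X[, t + 1L] <- x1
      Y[, t + 1L] <- y1
    }
    structure(list(config = config, x = X, y = Y, states = S,
                   stateNames = states, shelterActive = shelterOn,
                   weights = config$driverWeights),
              class = "SimTruth")
  })
}

#' @export
print.SimTruth <- function(x, ...) {
  cat(sprintf("SimTruth: %d animals x %d min; state occupancy: %s\n",
              nrow(x$x), ncol(x$states),
              paste(sprintf("%s %.0f%%", x$stateNames,
                            100 * tabulate(x$states, 3) / length(x$states)),
                    collapse = ", ")))
  invisible(x)
}

#' Observe simulated positions through the collar schedule
#'
#' Emits raw fixes at the burst offsets of each duty cycle (positions
#' linearly interpolated between minute nodes), adds positional jitter,
#' draws a time-to-fix with the configured probability of a slow
#' (> 16 s) fix, and drops fixes at the dropout rate — so the cleaning
#' step has genuine work to do. Emitted + dropped = scheduled.
#'
#' @param truth a [simulateFlock()] result.
#' @param config the same [simConfig()].
#' @return Raw fix table (animal_id, timestamp, easting, northing, ttf)
#'   with attributes `nScheduled` and `nDropped`.
#' @export
observeGps <- function(truth, config) {
  stopifnot(inherits(truth, "SimTruth"))
  sch <- config$schedule
  nMin <- ncol(truth$states)
  endS <- nMin * 60
  burst0 <- seq(0, endS - max(sch$burstOffsets), by = sch$cycle)
  tFix <- as.vector(outer(sch$burstOffsets, burst0, "+"))
  tFix <- sort(tFix[tFix < endS])            # the trial window is half-open
  nA <- nrow(truth$x)
  ids <- sprintf("A%02d", seq_len(nA))
  k <- floor(tFix / 60); frac <- tFix / 60 - k
  i0 <- k + 1L; i1 <- pmin(k + 2L, nMin + 1L)
  .withSeed(config$seed + 51L, {
    rows <- vector("list", nA)
    for (a in seq_len(nA)) {
      ex <- truth$x[a, i0] * (1 - frac) + truth$x[a, i1] * frac
      ny <- truth$y[a, i0] * (1 - frac) + truth$y[a, i1] * frac
      nFix <- length(tFix)
      ex <- ex + stats::rnorm(nFix, 0, config$jitterSD)
      ny <- ny + stats::rnorm(nFix, 0, config$jitterSD)
      slow <- stats::runif(nFix) < config$pSlowFix
      ttf <- ifelse(slow, 16 + stats::rexp(nFix, 1 / 8), stats::runif(nFix, 2, 16))
      keep <- stats::runif(nFix) >= config$dropout
      rows[[a]] <- data.frame(animal_id = ids[a],
                              timestamp = config$trialStart + tFix[keep],
                              easting = ex[keep], northing = ny[keep],
                              ttf = ttf[keep], stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "nScheduled") <- nA * length(tFix)
    attr(out, "nDropped") <- nA * length(tFix) - nrow(out)
    out
  })
}

#' Thin fixes to one per duty cycle
#'
#' Keeps the first retained fix of each animal in each collar cycle
#' (default 5 min), the usual mitigation of within-burst serial
#' autocorrelation before model fitting.
#'
#' @param fixes fix table.
#' @param trialStart POSIXct cycle reference.
#' @param cycle cycle length in seconds (default 300).
#' @return The thinned fix table.
#' @export
thinFixes <- function(fixes, trialStart, cycle = 300) {
  id <- fixes$animal_id %||% fixes$A          # fix tables vs model tables
  if (is.null(id)) stop("need an animal_id or A column")
  dt <- as.numeric(difftime(fixes$timestamp, trialStart, units = "secs"))
  key <- paste(id, floor(dt / cycle))
  fixes[!duplicated(key), , drop = FALSE]
}

#' Grazing observation intervals from simulation truth
#'
#' Emulates the scan-sampling record that defines the "grazing hours"
#' model subset: an hour counts as a grazing hour when at least
#' `minFraction` of the flock's animal-minutes that hour were spent in the
#' grazing state.
#'
#' @param truth a [simulateFlock()] result.
#' @param config the matching [simConfig()].
#' @param minFraction minimum grazing share of animal-minutes (default
#'   0.25).
#' @return data.frame of POSIXct `start`/`end` hour intervals.
#' @export
grazingIntervalsFromTruth <- function(truth, config, minFraction = 0.25) {
  grazeCode <- match("grazing", truth$stateNames)
  nMin <- ncol(truth$states)
  hourOf <- rep(seq_len(ceiling(nMin / 60)), each = 60L)[seq_len(nMin)]
  frac <- vapply(split(seq_len(nMin), hourOf), function(cols)
    mean(truth$states[, cols] == grazeCode), numeric(1L))
  hrs <- as.integer(names(frac))[frac >= minFraction]
  data.frame(start = config$trialStart + (hrs - 1L) * 3600,
             end = config$trialStart + hrs * 3600)
}

#' Named scenario library
#'
#' Ready-made simulation configurations for validation studies:
#' \describe{
#'   \item{ip-like}{improved-paddock pattern: sparse western tree row,
#'     north-west trough, gentle relief, residency dominated by NDVI
#'     (forage quality) in every state; 2 days.}
#'   \item{np-like}{native-paddock pattern: trees clustered in the north,
#'     south-west trough, 49 m elevation span, residency dominated by
#'     elevation and tree proximity (camping high under trees); 2 days.}
#'   \item{null}{all driver weights zero, no cohesion: an unbiased
#'     correlated random walk; 1 day.}
#'   \item{weather-driven}{mild forage weights, strong shelter weights
#'     that activate only when the hourly chill index exceeds the
#'     threshold; cold, windy, wet weather; 2 days.}
#' }
#'
#' @param name scenario name; `NULL` returns the whole named list.
#' @param seed master seed installed in the returned config(s).
#' @return A `SimConfig`, or a named list of them.
#' @export
scenarioLibrary <- function(name = NULL, seed = 1) {
  lib <- list(
    "ip-like" = simConfig(seed = seed, nDays = 2,
      treeLayout = "west-row", nTrees = 12, troughPosition = "northwest",
      elevRange = c(932, 949),
      driverWeights = list(resting = c(ndvi = 2), grazing = c(ndvi = 3),
                           travelling = c(ndvi = 1)),
      cohesion = 0.3),
    "np-like" = simConfig(seed = seed, nDays = 2,
      treeLayout = "clustered-north", nTrees = 40, troughPosition = "southwest",
      elevRange = c(935, 984),
      driverWeights = list(resting = c(el = 2.5, nt = -2),
                           grazing = c(el = 1.5, nt = -1, ndvi = 0.5),
                           travelling = c(el = 0.5)),
      cohesion = 0.3),
    "null" = simConfig(seed = seed, nDays = 1, cohesion = 0),
    "weather-driven" = simConfig(seed = seed, nDays = 2,
      driverWeights = list(resting = c(ndvi = 0.5, shelter = 2.5),
                           grazing = c(ndvi = 1, shelter = 2),
                           travelling = c(shelter = 1)),
      chillThreshold = 700,
      weather = list(tempMean = 4, tempAmp = 4, windMean = 7, windSD = 3,
                     rainEventProb = 0.1)))
  if (is.null(name)) return(lib)
  if (!name %in% names(lib))
    stop("unknown scenario '", name, "'; available: ",
         paste(names(lib), collapse = ", "))
  lib[[name]]
}

#' Run a scenario end to end
#'
#' Convenience pipeline for a single simulated paddock: generate landscape
#' and weather, simulate the flock, observe fixes through the collar
#' schedule, clean, assign hours, compute the treatment-level LRI, and
#' assemble the 12-predictor model table.
#'
#' @param scenario a scenario name (see [scenarioLibrary()]) or a
#'   [simConfig()].
#' @param seed optional seed override.
#' @return List: `config`, `landscape`, `weather`, `truth`, `rawFixes`,
#'   `fixes` (cleaned, with hours), `residency`, `table` (model table),
#'   `cleanReport`.
#' @export
simulateScenario <- function(scenario, seed = NULL) {
  config <- if (inherits(scenario, "SimConfig")) scenario
            else scenarioLibrary(scenario, seed = seed %||% 1)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  landscape <- generateLandscape(config)
  weather <- generateWeather(config)
  truth <- simulateFlock(landscape, weather, config)
  raw <- observeGps(truth, config)
  fixes <- cleanFixes(raw, landscape@boundary)
  rep <- cleanReport(fixes)
  fixes <- assignHours(fixes, config$trialStart)
  spec <- buildGrid(landscape@boundary, config$cellSize)
  residency <- computeLRI(fixes, spec, level = "treatment")
  tab <- assembleModelTable(fixes, residency, landscape, weather)
  list(config = config, landscape = landscape, weather = weather,
       truth = truth, rawFixes = raw, fixes = fixes, residency = residency,
       table = tab, cleanReport = rep)
}

#' Dominant simulated driver
#'
#' The model-table predictor corresponding to the largest-magnitude driver
#' weight of a configuration (grazing state first, then overall), or `NA`
#' for an all-zero (null) configuration.
#'
#' @param config a [simConfig()].
#' @return One of `"NDVI"`, `"EL"`, `"NT"`, `"NW"`, or `NA`.
#' @export
dominantDriver <- function(config) {
  map <- c(ndvi = "NDVI", el = "EL", nt = "NT", nw = "NW", shelter = "NT")
  tot <- Reduce(`+`, lapply(config$driverWeights, abs))
  if (all(tot == 0)) return(NA_character_)
  unname(map[names(which.max(tot))])
}

#' Simulate, fit and test drivers in one call
#'
#' The parameter-recovery harness: runs a scenario end to end, thins the
#' model rows to one fix per collar cycle, fits the residency forest on a
#' seeded subsample, and attaches target-permutation importance p-values.
#' Problem sizes default to a single-CPU budget (see the vignette).
#'
#' @param scenario scenario name or [simConfig()].
#' @param seed seed for the whole run.
#' @param nTrees,nPerm,fitRows forest size, target permutations, and fitted
#'   subsample size.
#' @param predictors predictor set (default all 12; drop `EA`/`NO` to
#'   probe spatial-proxy inflation).
#' @param computePValues set `FALSE` to skip the permutation test.
#' @return List: `fit` ([DriverFit-class]), `importance` (ranked table with
#'   p-values), `dominant` (the true driver), `oobR2`, `scenario` (the full
#'   [simulateScenario()] result).
#' @export
recoverDrivers <- function(scenario, seed = 1, nTrees = 100, nPerm = 100,
                           fitRows = 750, predictors = modelPredictors(),
                           computePValues = TRUE) {
  sim <- simulateScenario(scenario, seed = seed)
  tab <- thinFixes(sim$table, sim$config$trialStart,
                   cycle = sim$config$schedule$cycle)
  if (nrow(tab) > fitRows) {
    idx <- .withSeed(seed + 7L, sample.int(nrow(tab), fitRows))
    tab <- tab[idx, , drop = FALSE]
  }
  fit <- fitRF(tab, nTrees = nTrees, seed = seed, predictors = predictors,
               minRows = min(500, nrow(tab)))
  if (computePValues)
    fit <- importanceSignificance(tab, nPerm = nPerm, fit = fit,
                                  predictors = predictors)
  list(fit = fit, importance = rankImportance(fit),
       dominant = dominantDriver(sim$config), oobR2 = fit@oobR2,
       scenario = sim)
}
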