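# Random-forest residency driver models: OOB performance, permutation
# importance with target-permutation significance, rankings, partial
# dependence, and the per-trial/treatment study runner.

# integer-code the animal factor; all other predictors are numeric
.encodeTable <- function(rows, predictors, animalLevels = NULL) {
  x <- rows[, predictors, drop = FALSE]
  if ("A" %in% predictors) {
    if (is.null(animalLevels)) animalLevels <- sort(unique(as.character(x$A)))
    x$A <- as.integer(factor(as.character(x$A), levels = animalLevels))
  }
  list(x = as.data.frame(x), animalLevels = animalLevels %||% character(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate expr with a private RNG stream; the caller's RNG state is untouched
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Restrict a model table to observed grazing hours
#'
#' Keeps rows whose timestamp falls inside any observed grazing interval —
#' the "grazing hours" (GH) subset. The "all hours" (AH) model is simply
#' the unrestricted table.
#'
#' @param rows model table with a `timestamp` column.
#' @param intervals data.frame with POSIXct `start` and `end` columns;
#'   membership is half-open `[start, end)`.
#' @return The subset of `rows`, original order preserved.
#' @export
subsetGrazingHours <- function(rows, intervals) {
  stopifnot(is.data.frame(rows), "timestamp" %in% names(rows))
  if (is.null(intervals) || nrow(intervals) == 0L)
    stop("grazing-hours subsetting needs at least one grazing interval")
  t <- as.numeric(rows$timestamp)
  keep <- rep(FALSE, length(t))
  for (k in seq_len(nrow(intervals)))
    keep <- keep | (t >= as.numeric(intervals$start[k]) &
                    t < as.numeric(intervals$end[k]))
  rows[keep, , drop = FALSE]
}

#' Fit a residency random forest
#'
#' Regression forest of the LRI target on the 12 predictors, using
#' permutation variable importance. Performance is out-of-bag by default:
#' each row is predicted only by trees whose bootstrap sample excluded it,
#' bagging's internal ~2:1 calibration/validation split; `nCalibration` and
#' `nValidation` report that split's expected sizes (they sum to the rows
#' fitted). `splitMode = "holdout"` instead fits on an explicit 2/3 sample
#' and scores the held-out third.
#'
#' @param rows model table ([assembleModelTable()]).
#' @param nTrees number of trees (>= 100; default 500).
#' @param mtry predictors tried per split (default `floor(p / 3)`).
#' @param seed RNG seed; the fit is fully reproducible given it.
#' @param predictors predictor columns (default [modelPredictors()]).
#' @param target target column (default `"LRI"`).
#' @param trial,treatment,hoursMode identity labels stored on the fit.
#' @param minRows refuse to fit below this many rows (default 500).
#' @param splitMode `"oob"` (default) or `"holdout"`.
#' @return A [DriverFit-class].
#' @export
fitRF <- function(rows, nTrees = 500, mtry = NULL, seed = 1,
                  predictors = modelPredictors(), target = "LRI",
                  trial = NA_character_, treatment = NA_character_,
                  hoursMode = "AH", minRows = 500,
                  splitMode = c("oob", "holdout")) {
  splitMode <- match.arg(splitMode)
  stopifnot(is.data.frame(rows), target %in% names(rows))
  if (nTrees < 100) stop("use at least 100 trees")
  missingPred <- setdiff(predictors, names(rows))
  if (length(missingPred))
    stop("missing predictor column(s): ", paste(missingPred, collapse = ", "))
  if (nrow(rows) < minRows)
    stop(sprintf("only %d rows; need >= %d (lower minRows to override)",
                 nrow(rows), minRows))
  y <- rows[[target]]
  if (stats::var(y) == 0) stop("constant target: R-squared undefined")
  enc <- .encodeTable(rows, predictors)
  if (is.null(mtry)) mtry <- max(1L, floor(length(predictors) / 3))
  n <- nrow(rows)
  if (splitMode == "holdout") {
    idxCal <- .withSeed(seed, sample.int(n, floor(2 * n / 3)))
    rf <- ranger::ranger(x = enc$x[idxCal, , drop = FALSE], y = y[idxCal],
                         num.trees = nTrees, mtry = mtry,
                         importance = "permutation", seed = seed,
                         num.threads = 1)
    predVal <- predict(rf, data = enc$x[-idxCal, , drop = FALSE],
                       num.threads = 1)$predictions
    mse <- mean((predVal - y[-idxCal])^2)
    r2 <- 1 - mse / stats::var(y[-idxCal])
    nCal <- length(idxCal); nVal <- n - nCal
  } else {
    rf <- ranger::ranger(x = enc$x, y = y, num.trees = nTrees, mtry = mtry,
                         importance = "permutation", seed = seed,
                         num.threads = 1)
    pred <- rf$predictions
    ok <- is.finite(pred)                    # rows never OOB are excluded
    mse <- mean((pred[ok] - y[ok])^2)
    r2 <- 1 - mse / stats::var(y[ok])
    nCal <- as.integer(floor(n * (1 - exp(-1))))   # expected in-bag share
    nVal <- n - nCal
  }
  imp <- rf$variable.importance
  impTab <- rankImportance(imp)
  impTab$pValue <- NA_real_
  new("DriverFit", model = rf, trial = as.character(trial),
      treatment = as.character(treatment), hoursMode = hoursMode,
      predictors = predictors, animalLevels = enc$animalLevels,
      oobR2 = r2, oobMSE = mse, importance = impTab,
      nCalibration = as.integer(nCal), nValidation = as.integer(nVal),
      seed = as.integer(seed), nTrees = as.integer(nTrees),
      mtry = as.integer(mtry))
}

#' Permutation significance of variable importance
#'
#' Altmann-style target-permutation test: the target is permuted `nPerm`
#' times, the forest refit and the permutation importance recomputed each
#' time, and each predictor's p-value is
#' `(1 + #{null importance >= observed}) / (1 + nPerm)`. With the
#' conventional `nPerm = 100`, the smallest attainable p is 1/101, just
#' inside the alpha = 0.01 significance convention.
#'
#' @param rows model table.
#' @param nPerm number of target permutations (>= 20; default 100).
#' @param nTrees,mtry,seed,predictors,target,minRows as in [fitRF()].
#' @param fit optional already-fitted [DriverFit-class] on `rows` (saves
#'   the observed fit).
#' @return The [DriverFit-class] with the `pValue` column of its
#'   importance table filled in.
#' @export
importanceSignificance <- function(rows, nPerm = 100, nTrees = 500,
                                   mtry = NULL, seed = 1,
                                   predictors = modelPredictors(),
                                   target = "LRI", minRows = 500, fit = NULL) {
  if (nPerm < 20)
    stop("nPerm must be >= 20 for any resolution near alpha = 0.01")
  if (is.null(fit))
    fit <- fitRF(rows, nTrees = nTrees, mtry = mtry, seed = seed,
                 predictors = predictors, target = target, minRows = minRows)
  obs <- fit@model$variable.importance
  enc <- .encodeTable(rows, fit@predictors, fit@animalLevels)
  y <- rows[[target]]
  perms <- .withSeed(fit@seed + 104729L, replicate(nPerm, sample.int(length(y)),
                                                  simplify = FALSE))
  nullImp <- matrix(NA_real_, nPerm, length(obs),
                    dimnames = list(NULL, names(obs)))
  for (b in seq_len(nPerm)) {
    rfb <- ranger::ranger(x = enc$x, y = y[perms[[b]]], num.trees = fit@nTrees,
                          mtry = fit@mtry, importance = "permutation",
                          seed = fit@seed + b, num.threads = 1)
    nullImp[b, ] <- rfb$variable.importance[names(obs)]
  }
  p <- (1 + colSums(sweep(nullImp, 2L, obs, ">="))) / (1 + nPerm)
  imp <- fit@importance
  imp$pValue <- unname(p[imp$predictor])
  fit@importance <- imp
  fit
}

.ordinalLabel <- function(rank) {
  suffix <- ifelse(rank %% 100 %in% 11:13, "th",
                   c("st", "nd", "rd", rep("th", 7))[(rank - 1) %% 10 + 1])
  paste0(rank, suffix)
}

#' Rank predictors by importance
#'
#' Orders predictors by decreasing importance score, rank 1 being the most
#' important; exact ties are broken deterministically by predictor-name
#' order. Significance stars are attached at `p < alpha` when p-values are
#' available, giving Table-2-style labels like `"3rd *"`.
#'
#' @param x a [DriverFit-class], a named numeric vector of importance
#'   scores, or a data.frame with `predictor` and `importance` columns.
#' @param pValues optional named p-value vector (ignored for `DriverFit`,
#'   which carries its own).
#' @param alpha significance level for the star (default 0.01).
#' @return data.frame: predictor, importance, rank, pValue, significant,
#'   label; ordered by rank.
#' @export
rankImportance <- function(x, pValues = NULL, alpha = 0.01) {
  if (is(x, "DriverFit")) {
    imp <- stats::setNames(x@importance$importance, x@importance$predictor)
    pValues <- stats::setNames(x@importance$pValue, x@importance$predictor)
  } else if (is.data.frame(x)) {
    imp <- stats::setNames(x$importance, x$predictor)
  } else {
    imp <- x
  }
  stopifnot(!is.null(names(imp)))
  ord <- order(-imp, names(imp))
  rank <- integer(length(imp)); rank[ord] <- seq_along(imp)
  p <- if (is.null(pValues)) rep(NA_real_, length(imp)) else unname(pValues[names(imp)])
  sig <- !is.na(p) & p < alpha
  out <- data.frame(predictor = names(imp), importance = unname(imp),
                    rank = rank, pValue = p, significant = sig,
                    label = paste0(.ordinalLabel(rank), ifelse(sig, " *", "")),
                    stringsAsFactors = FALSE)
  out[order(out$rank), , drop = FALSE]
}

#' Partial dependence of the model on one predictor
#'
#' For each grid value g over the predictor's observed range, sets the
#' predictor to g in every training row, predicts, and averages: the
#' classical set-and-average partial dependence. The animal predictor `A`
#' is categorical, so its observed levels form the grid.
#'
#' @param object a [DriverFit-class], or any function
#'   `f(newdata) -> numeric` predictions.
#' @param data the model table the dependence is averaged over.
#' @param predictor predictor name.
#' @param nGrid grid resolution for numeric predictors (default 50).
#' @param grid optional explicit grid of predictor values.
#' @param sampleRows optional number of rows to average over (seeded
#'   subsample; `NULL` = all rows).
#' @param seed seed for `sampleRows`.
#' @return data.frame: `value` (grid) and `yhat` (mean prediction), with
#'   the predictor name as attribute `predictor`.
#' @export
partialDependence <- function(object, data, predictor, nGrid = 50, grid = NULL,
                              sampleRows = NULL, seed = 1) {
  stopifnot(is.data.frame(data))
  if (is(object, "DriverFit")) {
    stopifnot(predictor %in% object@predictors)
    enc <- .encodeTable(data, object@predictors, object@animalLevels)
    base <- enc$x
    predictFun <- function(nd) predict(object@model, data = nd,
                                       num.threads = 1)$predictions
    isCat <- predictor == "A"
  } else {
    stopifnot(is.function(object), predictor %in% names(data))
    base <- data
    predictFun <- object
    isCat <- is.factor(data[[predictor]]) || is.character(data[[predictor]])
  }
  if (!is.null(sampleRows) && sampleRows < nrow(base)) {
    idx <- .withSeed(seed, sample.int(nrow(base), sampleRows))
    base <- base[idx, , drop = FALSE]
  }
  if (is.null(grid)) {
    v <- base[[predictor]]
    grid <- if (isCat) sort(unique(v))
            else seq(min(v), max(v), length.out = nGrid)
  }
  yhat <- vapply(grid, function(g) {
    nd <- base
    nd[[predictor]] <- if (is.factor(nd[[predictor]]))
      factor(g, levels = levels(nd[[predictor]])) else g
    mean(predictFun(nd))
  }, numeric(1L))
  out <- data.frame(value = grid, yhat = yhat)
  attr(out, "predictor") <- predictor
  out
}

#' Fit the full model suite for a study
#'
#' Fits one random forest per trial x treatment x hours-mode cell — the
#' classical 4 x 2 x {AH, GH} = 16-model layout — and collects a
#' performance table (OOB R2, MSE, calibration/validation sizes) and a
#' 12-predictor x model ranking table. Cells with no grazing observations
#' (GH impossible) or too few rows are skipped with a warning.
#'
#' @param tables named list of model tables; names are `"<trial>_<treatment>"`
#'   (e.g. `"T1_IP"`).
#' @param grazingIntervals named list (same names) of grazing-interval
#'   data.frames for [subsetGrazingHours()]; `NULL` entries skip that GH
#'   model.
#' @param nTrees,mtry,seed,minRows as in [fitRF()].
#' @param fitRows optional per-model row cap: larger tables are fitted on a
#'   seeded subsample of this size (a computing-budget control; `NULL` uses
#'   every row).
#' @param computePValues run [importanceSignificance()] per model (slow).
#' @param nPerm permutations when `computePValues = TRUE`.
#' @param outDir optional directory; writes `performance.csv`,
#'   `rankings.csv` and a JSON run manifest.
#' @return List: `performance` (data.frame), `rankings` (12 x models
#'   data.frame of rank labels), `fits` (named list of
#'   [DriverFit-class]), `skipped` (character).
#' @export
runStudy <- function(tables, grazingIntervals = NULL, nTrees = 500, mtry = NULL,
                     seed = 1, minRows = 500, fitRows = NULL,
                     computePValues = FALSE, nPerm = 100, outDir = NULL) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  fits <- list(); skipped <- character(0)
  perf <- list()
  for (key in names(tables)) {
    parts <- strsplit(key, "_", fixed = TRUE)[[1L]]
    trial <- parts[1L]; treatment <- parts[2L]
    for (mode in c("AH", "GH")) {
      label <- paste(key, mode, sep = "_")
      rows <- tables[[key]]
      if (mode == "GH") {
        iv <- grazingIntervals[[key]]
        if (is.null(iv) || nrow(iv) == 0L) {
          warning("no grazing intervals for ", key, "; skipping GH model")
          skipped <- c(skipped, label)
          next
        }
        rows <- subsetGrazingHours(rows, iv)
      }
      if (nrow(rows) < minRows) {
        warning(label, ": only ", nrow(rows), " rows; model skipped")
        skipped <- c(skipped, label)
        next
      }
      if (!is.null(fitRows) && nrow(rows) > fitRows) {
        idx <- .withSeed(seed + length(fits), sample.int(nrow(rows), fitRows))
        rows <- rows[idx, , drop = FALSE]
      }
      fit <- fitRF(rows, nTrees = nTrees, mtry = mtry, seed = seed,
                   trial = trial, treatment = treatment, hoursMode = mode,
                   minRows = minRows)
      if (computePValues)
        fit <- importanceSignificance(rows, nPerm = nPerm, fit = fit)
      fits[[label]] <- fit
      perf[[label]] <- data.frame(model = label, trial = trial,
                                  treatment = treatment, hours_mode = mode,
                                  oob_r2 = fit@oobR2, oob_mse = fit@oobMSE,
                                  n_cal = fit@nCalibration,
                                  n_val = fit@nValidation,
                                  stringsAsFactors = FALSE)
    }
  }
  performance <- do.call(rbind, perf)
  rownames(performance) <- NULL
  rankings <- data.frame(Variable = modelPredictors(), stringsAsFactors = FALSE)
  for (label in names(fits)) {
    tab <- fits[[label]]@importance
    rankings[[label]] <- tab$label[match(rankings$Variable, tab$predictor)]
  }
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(performance, file.path(outDir, "performance.csv"),
                     row.names = FALSE)
    utils::write.csv(rankings, file.path(outDir, "rankings.csv"),
                     row.names = FALSE)
    manifest <- list(seed = seed, nTrees = nTrees,
                     mtry = mtry %||% floor(length(modelPredictors()) / 3),
                     fitRows = fitRows, computePValues = computePValues,
                     nPerm = if (computePValues) nPerm else NULL,
                     models = names(fits), skipped = skipped,
                     timestamp = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
  }
  list(performance = performance, rankings = rankings, fits = fits,
       skipped = skipped)
}
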