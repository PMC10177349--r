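# synthetic covariate table with a controllable target
makeTable <- function(n, seed = 1, noiseSD = 0,
                      f = function(d) sin(2 * pi * d$NDVI) + 0.5 * d$EL) {
  set.seed(seed)
  d <- data.frame(A = sample(sprintf("A%02d", 1:15), n, replace = TRUE),
                  EA = runif(n, 0, 500), NO = runif(n, 0, 450),
                  NT = runif(n, 0, 300), NW = runif(n, 0, 600),
                  NF = runif(n, 0, 100), NDVI = runif(n, 0.1, 0.4),
                  AS = runif(n, 0, 360), EL = runif(n, 0, 1),
                  T = runif(n, -5, 25), R = rexp(n, 2),
                  WC = runif(n, 400, 1000), stringsAsFactors = FALSE)
  d$timestamp <- as.POSIXct("2014-04-23", tz = "UTC") + seq_len(n) * 60
  d$LRI <- f(d) + rnorm(n, 0, noiseSD)
  d
}

test_that("grazing-hours subsetting matches interval membership", {
  d <- makeTable(200)
  start <- as.POSIXct("2014-04-23", tz = "UTC")
  all <- data.frame(start = start, end = start + 1e7)
  expect_equal(nrow(subsetGrazingHours(d, all)), 200)
  one <- data.frame(start = start + 3600, end = start + 7200)
  got <- subsetGrazingHours(d, one)
  expect_true(all(got$timestamp >= one$start & got$timestamp < one$end))
  set.seed(81)
  iv <- data.frame(start = start + sort(sample(0:200, 4)) * 60)
  iv$end <- iv$start + c(600, 300, 900, 1200)
  got2 <- subsetGrazingHours(d, iv)
  t <- as.numeric(d$timestamp)
  oracle <- sapply(t, function(ti)
    any(ti >= as.numeric(iv$start) & ti < as.numeric(iv$end)))
  expect_equal(nrow(got2), sum(oracle))
  expect_error(subsetGrazingHours(d, NULL), "interval")
})

test_that("the forest recovers a strong deterministic signal and not pure noise", {
  d <- makeTable(5000, seed = 82, noiseSD = 0)
  fit <- fitRF(d, nTrees = 300, seed = 1)
  expect_gte(oobR2(fit), 0.9)
  r2null <- sapply(1:5, function(s) {
    dn <- makeTable(1500, seed = 100 + s, f = function(d) rnorm(nrow(d)))
    oobR2(fitRF(dn, nTrees = 200, seed = s))
  })
  expect_true(all(r2null <= 0.1))
  expect_error(fitRF(transform(d, LRI = 1), nTrees = 100), "constant target")
  expect_error(fitRF(d[1:100, ], nTrees = 100), "need >=")
})

test_that("fitting is reproducible given the seed and books its split sizes", {
  d <- makeTable(1200, seed = 83, noiseSD = 0.1)
  f1 <- fitRF(d, nTrees = 150, seed = 9)
  f2 <- fitRF(d, nTrees = 150, seed = 9)
  expect_identical(oobR2(f1), oobR2(f2))
  expect_identical(importanceTable(f1)$importance, importanceTable(f2)$importance)
  expect_equal(f1@nCalibration + f1@nValidation, nrow(d))
  expect_equal(f1@nCalibration / nrow(d), 1 - exp(-1), tolerance = 0.01)
  expect_equal(sort(importanceTable(f1)$rank), 1:12)
  # holdout mode books an explicit 2:1 split
  fh <- fitRF(d, nTrees = 150, seed = 9, splitMode = "holdout")
  expect_equal(fh@nCalibration, floor(2 * nrow(d) / 3))
  expect_lte(abs(oobR2(fh) - oobR2(f1)), 0.2)
})

test_that("both R-squared conventions order model quality the same way", {
  strong <- fitRF(makeTable(2000, seed = 84, noiseSD = 0.05), nTrees = 200, seed = 1)
  weak <- fitRF(makeTable(2000, seed = 85, noiseSD = 2), nTrees = 200, seed = 1)
  corR2 <- function(fit, d) {
    p <- fit@model$predictions
    ok <- is.finite(p)
    cor(p[ok], d$LRI[ok])^2
  }
  d1 <- makeTable(2000, seed = 84, noiseSD = 0.05)
  d2 <- makeTable(2000, seed = 85, noiseSD = 2)
  expect_gt(oobR2(strong), oobR2(weak))
  expect_gt(corR2(strong, d1), corR2(weak, d2))
})

test_that("target-permutation p-values separate signal from injected noise", {
  d <- makeTable(800, seed = 86, noiseSD = 0.05)
  fit <- importanceSignificance(d, nPerm = 50, nTrees = 100, seed = 3, minRows = 500)
  imp <- importanceTable(fit)
  expect_true(all(imp$pValue >= 1 / 51 & imp$pValue <= 1))
  expect_lte(imp$pValue[imp$predictor == "NDVI"], 0.02)   # the true driver
  expect_gt(imp$pValue[imp$predictor == "NF"], 0.05)      # pure noise column
  expect_error(importanceSignificance(d, nPerm = 10), ">= 20")
  # p-value arithmetic: p = (1 + #(null >= obs)) / (1 + B)
  nulls <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal((1 + sum(nulls >= 0.25)) / (1 + length(nulls)), 0.6)
})

test_that("ranking is dense, deterministic under ties, and starred at p < 0.01", {
  r <- rankImportance(c(b = 2, a = 3, c = 1))
  expect_equal(r$predictor, c("a", "b", "c"))
  expect_equal(r$rank, 1:3)
  tie <- rankImportance(c(z = 1, y = 1, x = 2))
  expect_equal(tie$predictor, c("x", "y", "z"))       # name order breaks the tie
  starred <- rankImportance(c(a = 5, b = 1), pValues = c(a = 0.005, b = 0.5))
  expect_equal(starred$label, c("1st *", "2nd"))
  expect_equal(rankImportance(setNames(12:1, letters[1:12]))$label[11:12],
               c("11th", "12th"))
})

test_that("partial dependence equals brute-force set-and-average", {
  skip_if_not_installed("rpart")
  d <- makeTable(400, seed = 87, noiseSD = 0.1)
  stump <- rpart::rpart(LRI ~ NDVI, data = d,
                        control = rpart::rpart.control(maxdepth = 1, cp = 0))
  predFun <- function(nd) unname(predict(stump, newdata = nd))
  pd <- partialDependence(predFun, d, "NDVI", nGrid = 21)
  oracle <- vapply(pd$value, function(g) {
    nd <- d; nd$NDVI <- g
    mean(predict(stump, newdata = nd))
  }, numeric(1))
  expect_equal(pd$yhat, oracle, tolerance = 1e-12)
  expect_equal(length(unique(round(pd$yhat, 9))), 2)  # a stump is a step function
  # a constant model has a flat curve
  flat <- partialDependence(function(nd) rep(3.7, nrow(nd)), d, "EL")
  expect_true(all(flat$yhat == 3.7))
})

test_that("forest partial dependence stays within prediction bounds", {
  d <- makeTable(800, seed = 88, noiseSD = 0.05)
  fit <- fitRF(d, nTrees = 150, seed = 2)
  pd <- partialDependence(fit, d, "NDVI", nGrid = 25)
  allPred <- predict(fit@model, data = grazeRF:::.encodeTable(
    d, fit@predictors, fit@animalLevels)$x, num.threads = 1)$predictions
  expect_true(all(pd$yhat >= min(allPred) - 1e-12))
  expect_true(all(pd$yhat <= max(allPred) + 1e-12))
  expect_true(!is.unsorted(pd$value))
  # categorical animal predictor uses its levels as the grid
  pdA <- partialDependence(fit, d, "A")
  expect_equal(nrow(pdA), length(unique(d$A)))
})

test_that("permutation p-values are super-uniform under a global null", {
  # target drawn independently of every predictor: P(p <= t) must not
  # exceed t beyond Kolmogorov-Smirnov noise (~1.36/sqrt(n) at n = 204)
  set.seed(9)
  ps <- c()
  for (r in 1:17) {
    n <- 250
    d <- data.frame(matrix(rnorm(n * 12), n, 12))
    names(d) <- modelPredictors()
    d$A <- sample(sprintf("A%02d", 1:10), n, TRUE)
    d$LRI <- rnorm(n)
    fit <- importanceSignificance(d, nPerm = 30, nTrees = 100, seed = r,
                                  minRows = 100)
    ps <- c(ps, importanceTable(fit)$pValue)
  }
  grid <- seq(0.05, 0.95, by = 0.05)
  excess <- vapply(grid, function(t) mean(ps <= t) - t, numeric(1))
  expect_lt(max(excess), 1.36 / sqrt(length(ps)))
})

test_that("runStudy fits the trial-by-treatment suite and shapes its tables", {
  tabs <- list(T1_IP = makeTable(900, seed = 89, noiseSD = 0.1),
               T1_NP = makeTable(900, seed = 90, noiseSD = 0.1))
  start <- as.POSIXct("2014-04-23", tz = "UTC")
  iv <- data.frame(start = start, end = start + 2e5)
  study <- runStudy(tabs, grazingIntervals = list(T1_IP = iv, T1_NP = iv),
                    nTrees = 100, seed = 4, minRows = 200)
  expect_equal(nrow(study$performance), 4)            # 2 tables x AH/GH
  expect_setequal(study$performance$hours_mode, c("AH", "GH"))
  expect_equal(dim(study$rankings), c(12, 5))         # Variable + 4 models
  expect_equal(study$performance$n_cal + study$performance$n_val,
               rep(900L, 4))
  # a table without grazing intervals skips GH with a warning
  expect_warning(s2 <- runStudy(tabs["T1_IP"], nTrees = 100, seed = 4,
                                minRows = 200), "skipping GH")
  expect_equal(s2$skipped, "T1_IP_GH")
})
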