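test_that("NIPALS PLS recovers exact univariate and full-rank solutions", {
  # univariate: y = 2 x -> beta = 2, intercept consistent with the means
  set.seed(1)
  x <- matrix(rnorm(30), ncol = 1)
  y <- 2 * x[, 1]
  m <- fitPLSDA(x, y, nLV = 1)
  expect_equal(coefVector(m), c(`1` = 2), tolerance = 1e-10)
  expect_equal(intercept(m), mean(y) - 2 * mean(x), tolerance = 1e-10)

  # at full rank, PLS equals the normal-equations least-squares solution
  for (rep in 1:3) {
    set.seed(rep)
    X <- matrix(rnorm(50 * 5), 50, 5)
    y <- rnorm(50)
    m <- fitPLSDA(X, y, nLV = 5)
    Xc <- sweep(X, 2, colMeans(X))
    betaOLS <- solve(crossprod(Xc), crossprod(Xc, y - mean(y)))
    expect_equal(m@beta, as.numeric(betaOLS), tolerance = 1e-8)
  }

  # row-order invariance
  set.seed(9)
  X <- matrix(rnorm(40 * 6), 40, 6); y <- rep(c(0, 1), 20)
  m1 <- fitPLSDA(X, y, nLV = 3)
  perm <- sample(40)
  m2 <- fitPLSDA(X[perm, ], y[perm], nLV = 3)
  expect_equal(m1@beta, m2@beta, tolerance = 1e-10)

  expect_error(fitPLSDA(X, rep(1, 40), nLV = 2), "degenerate target")
  expect_error(fitPLSDA(X, y, nLV = 50), "between 1 and")
})

test_that("factor and beta prediction routes agree on training data", {
  tab <- syntheticTable(nSeedsPerClass = 5, pixelsPerSeed = 8, p = 10)
  m <- fitPLSDA(tab, nLV = 4)
  viaFactors <- m@yMean + as.numeric(m@scores %*% m@q)
  viaBeta <- predictPixels(m, spectraMatrix(tab))$scores
  expect_equal(viaFactors, viaBeta, tolerance = 1e-8)
})

test_that("RMSECV latent-variable selection is deterministic and well-shaped", {
  tab <- syntheticTable(nSeedsPerClass = 6, pixelsPerSeed = 10, p = 12,
                        sep = 2, noise = 0.3)
  m <- selectLatentVariables(tab, maxLV = 6, nFolds = 4, seed = 3)
  curve <- rmsecvCurve(m)
  expect_length(curve, 6L)
  expect_true(all(is.finite(curve) & curve >= 0))
  # one informative direction: the choice lands small
  expect_lte(nLatent(m), 3L)
  expect_lte(curve[nLatent(m)], curve[1])

  m2 <- selectLatentVariables(tab, maxLV = 6, nFolds = 4, seed = 3)
  expect_identical(nLatent(m2), nLatent(m))
  expect_identical(m2@beta, m@beta)
  expect_identical(rmsecvCurve(m2), curve)

  # infeasible maxLV is clipped with a warning
  expect_warning(mClip <- selectLatentVariables(tab, maxLV = 50, nFolds = 4,
                                                seed = 3), "clipped")
  expect_lte(nLatent(mClip), 12L)
})

test_that("pixel prediction uses the strict 0.5 rule", {
  tab <- syntheticTable()
  m <- fitPLSDA(tab, nLV = 2)
  # force known score structure
  m@beta <- rep(0, length(m@beta)); m@b0 <- 0.5
  expect_true(all(predictPixels(m, spectraMatrix(tab))$classes == 0L))
  m@b0 <- 0.7
  expect_true(all(predictPixels(m, spectraMatrix(tab))$classes == 1L))
  m@b0 <- 0.5 + 1e-12
  expect_true(all(predictPixels(m, spectraMatrix(tab))$classes == 1L))

  # well-separated classes are nearly perfectly classified
  sepTab <- syntheticTable(nSeedsPerClass = 10, pixelsPerSeed = 10, sep = 5,
                           noise = 0.3)
  ms <- fitPLSDA(sepTab, nLV = 2)
  pred <- predictPixels(ms, spectraMatrix(sepTab))
  expect_gte(mean(pred$classes == pixelClasses(sepTab)), 0.99)

  expect_error(predictPixels(ms, matrix(0, 3, 4)), "band mismatch")
})

test_that("pixel accuracy table reports per-class and total rates", {
  perfect <- pixelAccuracy(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(perfect$accuracy_pct, c(100, 100, 100))
  allOnes <- pixelAccuracy(rep(1, 10), rep(c(1, 0), each = 5))
  expect_equal(allOnes$accuracy_pct, c(100, 0, 50))
  hand <- pixelAccuracy(c(1, 1, 1, 1, 0, 0, 0, 1, 0, 0),
                        c(1, 1, 1, 1, 0, 0, 0, 0, 1, 1))
  expect_equal(hand$accuracy_pct[3], 70)
  expect_error(pixelAccuracy(integer(0), integer(0)), "non-empty")
})

test_that("VIP scores obey the normalization identity and the formula", {
  # uniform weights in a single component: VIP identically 1
  p <- 6
  m <- new("PLSDAModel", nLV = 1L, W = matrix(1 / sqrt(p), p, 1),
           P = matrix(1, p, 1), scores = matrix(rnorm(10), 10, 1),
           q = 0.7, beta = rep(0.1, p), b0 = 0, xMean = rep(0, p),
           yMean = 0.5, rmsecv = numeric(0),
           wavelength = seq(1000, 1500, 100), threshold = 0.5)
  expect_equal(vipValues(vipScores(m)), rep(1, p), tolerance = 1e-12)

  # fitted models: mean of squared scores is 1; formula matches the oracle
  for (s in 1:3) {
    tab <- syntheticTable(nSeedsPerClass = 4, pixelsPerSeed = 6, p = 9,
                          seed = s)
    mf <- fitPLSDA(tab, nLV = 3)
    v <- vipScores(mf)
    expect_equal(mean(vipValues(v)^2), 1, tolerance = 1e-10)
    expect_equal(sum(vipValues(v)^2), 9, tolerance = 1e-10)
    expect_equal(vipValues(v), vipOracle(mf), tolerance = 1e-12)
  }

  # two-band toy: only band 1 carries signal -> VIP_1 > 1 > VIP_2
  set.seed(2)
  X <- cbind(rep(c(0, 1), each = 20) + rnorm(40, sd = 0.1), rnorm(40, sd = 0.1))
  m2 <- fitPLSDA(X, rep(c(0, 1), each = 20), nLV = 1)
  v2 <- vipValues(vipScores(m2))
  expect_gt(v2[1], 1); expect_lt(v2[2], 1)
})

test_that("waveband selection keeps >1 peaks and eligible endpoints", {
  mkVIP <- function(scores) {
    scores <- scores * sqrt(length(scores) / sum(scores^2))  # normalize
    new("VIPResult", scores = scores,
        wavelength = seq(1000, by = 10, length.out = length(scores)),
        selected = numeric(0), rule = list())
  }
  # flat curve at exactly 1: strict > 1 excludes everything
  expect_warning(flat <- selectWavebands(mkVIP(rep(1, 8))), "empty")
  expect_length(selectedBands(flat), 0L)

  # single triangular peak
  tri <- c(0.5, 0.6, 0.9, 2, 0.9, 0.6, 0.5, 0.4)
  vip <- selectWavebands(mkVIP(tri))
  sel <- selectedBands(vip)
  # normalization scales everything; the peak band is index 4
  expect_equal(sel, 1030)

  # endpoints above 1 are included even though they cannot be interior peaks
  ends <- c(3, 0.4, 0.4, 0.4, 0.4, 0.4, 0.4, 3)
  expect_equal(selectedBands(selectWavebands(mkVIP(ends))), c(1000, 1070))

  # minimum separation drops the weaker of two nearby peaks
  pair <- c(0.1, 2.0, 0.5, 1.9, 0.1, 0.1, 0.1, 0.1)
  selPair <- selectedBands(selectWavebands(mkVIP(pair), minSeparation = 3L))
  expect_equal(selPair, 1010)

  # cap on the number of bands keeps the strongest
  many <- c(2.5, 0.1, 2.0, 0.1, 1.8, 0.1, 1.6, 0.1)
  capped <- selectedBands(selectWavebands(mkVIP(many), maxBands = 2L))
  expect_length(capped, 2L)
  expect_true(1000 %in% capped)
})

test_that("refitting on a band subset reproduces or restricts the model", {
  tab <- syntheticTable(nSeedsPerClass = 5, pixelsPerSeed = 8, p = 8,
                        sep = 2, noise = 0.3)
  full <- selectLatentVariables(tab, maxLV = 4, nFolds = 4, seed = 2)
  same <- refitOnBands(tab, wavelengths(tab), maxLV = 4, nFolds = 4, seed = 2)
  expect_identical(same@beta, full@beta)
  expect_identical(nLatent(same), nLatent(full))

  oneBand <- refitOnBands(tab, wavelengths(tab)[1], maxLV = 4, nFolds = 4,
                          seed = 2)
  expect_identical(nLatent(oneBand), 1L)
  expect_length(oneBand@beta, 1L)

  expect_error(refitOnBands(tab, 1234.5, maxLV = 4), "not on the table")
})

test_that("model JSON serialization round-trips", {
  tab <- syntheticTable()
  m <- fitPLSDA(tab, nLV = 2)
  path <- withr::local_tempfile(fileext = ".json")
  saveModel(m, path)
  back <- loadModel(path)
  expect_equal(back@beta, m@beta)
  expect_equal(back@b0, m@b0)
  expect_equal(back@W, m@W, ignore_attr = TRUE)
  expect_equal(predictPixels(back, spectraMatrix(tab))$scores,
               predictPixels(m, spectraMatrix(tab))$scores)
})
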