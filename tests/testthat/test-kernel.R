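kernelFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sc <- renderScene(tinyScene(nRows = 2L, nCols = 2L))
      refl <- calibrateReflectance(sc$raw, sc$frames)
      pre <- applyPretreatment(refl, pretreatmentSpec("snv"),
                               labelMatrix(sc$truth) > 0L)
      tab <- extractSpectra(pre, sc$truth)
      model <- fitPLSDA(tab, nLV = 2)
      cache <<- list(sc = sc, pre = pre, tab = tab, model = model)
    }
    cache
  }
})

test_that("chemical image scores match pixel prediction and mask the background", {
  fx <- kernelFixture()
  chem <- chemicalImage(fx$pre, fx$sc$truth, fx$model)
  fg <- labelMatrix(fx$sc$truth) > 0L
  expect_true(all(is.na(chem@values[!fg])))
  expect_true(all(is.na(chem@binary[!fg])))

  # row-for-row consistency with predictPixels on the extracted table
  pred <- predictPixels(fx$model, fx$tab)
  # raster-scan order of the table vs column-major image storage
  ord <- order(rep(seq_len(nrow(fg)), times = ncol(fg))[fg],
               rep(seq_len(ncol(fg)), each = nrow(fg))[fg])
  expect_equal(chem@values[fg][ord], pred$scores, tolerance = 1e-12)

  # constant-score cubes exercise the strict boundary
  m <- fx$model
  m@beta <- rep(0, length(m@beta)); m@b0 <- 1
  allOn <- chemicalImage(fx$pre, fx$sc$truth, m)
  expect_true(all(allOn@binary[fg]))
  m@b0 <- 0.5
  boundary <- chemicalImage(fx$pre, fx$sc$truth, m)
  expect_false(any(boundary@binary[fg]))
})

test_that("detection rates count detected pixels per seed exactly", {
  fx <- kernelFixture()
  chem <- chemicalImage(fx$pre, fx$sc$truth, fx$model)
  rates <- detectionRates(chem, fx$sc$truth)
  expect_equal(nrow(rates), nSeeds(fx$sc$truth))
  expect_equal(rates$detection_pct, 100 * rates$n_detected / rates$n_total)
  expect_true(all(rates$detection_pct >= 0 & rates$detection_pct <= 100))
  # conservation: summed detections equal the true pixels of the binary image
  expect_equal(sum(rates$n_detected), sum(chem@binary, na.rm = TRUE))
  expect_equal(sum(rates$n_total), sum(labelMatrix(fx$sc$truth) > 0L))
})

test_that("the seed rule is inclusive at the detection-rate threshold", {
  # 100-pixel seed with k detected at rate 50%: viable iff k >= 50
  dec <- makeDecisions(viableRates = c(50, 49), nonviableRates = numeric(0))
  out <- classifySeeds(dec, 50)
  expect_identical(out$predicted_class, c(1L, 0L))

  # rate 0 -> every seed viable
  dec2 <- makeDecisions(c(0, 10), c(0, 99))
  expect_true(all(classifySeeds(dec2, 0)$predicted_class == 1L))
  expect_error(classifySeeds(dec2, 101), "detectionRate")
})

test_that("ROC agrees with the Mann-Whitney oracle and is monotone", {
  # perfectly separated rates
  sep <- makeDecisions(c(80, 90, 95), c(5, 10, 20))
  expect_equal(rocAUC(rocCurve(sep)), 1.0)

  # identical rates for all seeds: uninformative
  flat <- makeDecisions(c(40, 40), c(40, 40))
  expect_equal(rocAUC(rocCurve(flat)), 0.5)

  # random instances match pairwise counting exactly
  set.seed(7)
  for (i in 1:20) {
    rates <- round(runif(12, 0, 100), 1)
    truth <- sample(rep(c(0L, 1L), 6))
    dec <- data.frame(seed_id = 1:12, n_total = 100L,
                      n_detected = 0L, detection_pct = rates,
                      predicted_class = NA_integer_, true_class = truth)
    roc <- rocCurve(dec)
    expect_equal(rocAUC(roc), aucOracle(rates, truth), tolerance = 1e-12)
    # monotone sensitivity/specificity along the threshold sweep
    cv <- rocTable(roc)
    cv <- cv[order(cv$threshold), ]
    expect_true(all(diff(cv$sensitivity) <= 1e-12))
    expect_true(all(diff(cv$specificity) >= -1e-12))
  }

  oneClass <- makeDecisions(c(10, 20), numeric(0))
  expect_error(rocCurve(oneClass), "both true classes")
})

test_that("the optimal detection rate minimizes FP+FN with documented ties", {
  # any threshold in (20, 80] is perfect; ties resolve to the largest, 80
  roc <- rocCurve(makeDecisions(c(80, 90), c(10, 20)))
  expect_equal(optimalDetectionRate(roc), 80)
  expect_equal(unname(rocAUC(roc)), 1)

  # degenerate separable case: viable at 100, nonviable at 0 -> 100
  roc2 <- rocCurve(makeDecisions(c(100, 100), c(0, 0)))
  expect_equal(optimalDetectionRate(roc2), 100)

  # the optimum is never worse than the 50% default in FP+FN
  set.seed(3)
  for (i in 1:10) {
    dec <- makeDecisions(runif(6, 30, 100), runif(6, 0, 70))
    roc <- rocCurve(dec)
    cost <- function(rate) {
      cl <- classifySeeds(dec, rate)
      sum(cl$predicted_class != cl$true_class)
    }
    expect_lte(cost(optimalDetectionRate(roc)), cost(50))
  }
})

test_that("seed accuracy table mirrors the per-class convention", {
  dec <- classifySeeds(makeDecisions(c(80, 90, 60, 20), c(10, 20)), 50)
  acc <- seedAccuracy(dec)
  expect_equal(acc$accuracy_pct, c(75, 100, 5 / 6 * 100))
  perfect <- classifySeeds(makeDecisions(c(90, 95), c(5, 10)), 50)
  expect_equal(seedAccuracy(perfect)$accuracy_pct, c(100, 100, 100))
  bad <- makeDecisions(c(90), c(10))
  expect_error(seedAccuracy(bad), "classifySeeds")
})

test_that("result maps are red/green/black, deterministic and class-swappable", {
  fx <- kernelFixture()
  lmap <- fx$sc$truth
  chem <- chemicalImage(fx$pre, lmap, fx$model)
  dec <- classifySeeds(detectionRates(chem, lmap), 50)
  tmp <- withr::local_tempdir()
  p1 <- file.path(tmp, "map.png")
  renderResultMap(lmap, dec, p1)
  img <- png::readPNG(p1)
  lab <- labelMatrix(lmap)
  viable <- lab > 0L & matrix(dec$predicted_class[pmax(lab, 1)] == 1L,
                              nrow(lab), ncol(lab))
  nonviable <- lab > 0L & !viable
  expect_true(all(img[, , 1][viable] == 1) && all(img[, , 2][viable] == 0))
  expect_true(all(img[, , 2][nonviable] == 1) && all(img[, , 1][nonviable] == 0))
  expect_true(all(img[, , 1][lab == 0L] == 0) && all(img[, , 3] == 0))

  # deterministic bytes
  p2 <- file.path(tmp, "map2.png")
  renderResultMap(lmap, dec, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))

  # flipping every class swaps the color planes
  flip <- dec; flip$predicted_class <- 1L - flip$predicted_class
  p3 <- file.path(tmp, "map3.png")
  renderResultMap(lmap, flip, p3)
  img3 <- png::readPNG(p3)
  expect_equal(img3[, , 1], img[, , 2])
  expect_equal(img3[, , 2], img[, , 1])
})
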