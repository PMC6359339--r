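test_that("threshold mask follows the configured polarity", {
  band <- matrix(c(0.1, 0.2, 0.9, 0.8), 2, 2)
  expect_identical(thresholdMask(band, 0.5),
                   matrix(c(FALSE, FALSE, TRUE, TRUE), 2, 2))
  expect_identical(thresholdMask(band, 0.5, seedsAbove = FALSE),
                   matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2))
  expect_true(all(thresholdMask(band, 0)))      # below min -> all foreground
  expect_false(any(thresholdMask(band, 1)))     # above max -> all background
})

test_that("seed labeling is 8-connected with small components removed", {
  mask <- matrix(FALSE, 10, 12)
  mask[2:4, 2:4] <- TRUE
  mask[6:8, 8:10] <- TRUE
  lmap <- labelSeeds(mask, minSeedPixels = 5L)
  expect_equal(nSeeds(lmap), 2L)
  # raster-scan ID order: top-left blob is seed 1
  expect_equal(labelMatrix(lmap)[2, 2], 1L)
  expect_equal(labelMatrix(lmap)[6, 8], 2L)

  # diagonal contact joins components
  diagMask <- matrix(FALSE, 6, 6)
  diagMask[cbind(1:4, 1:4)] <- TRUE
  expect_equal(nSeeds(labelSeeds(diagMask, 1L)), 1L)

  # component below the size floor is removed; empty scene errors
  small <- matrix(FALSE, 5, 5)
  small[2:3, 2:3] <- TRUE
  expect_error(labelSeeds(small, minSeedPixels = 10L), "empty scene")
  expect_equal(nSeeds(labelSeeds(small, minSeedPixels = 4L)), 1L)
})

test_that("row-layout class assignment bins centroids into grid rows", {
  mask <- matrix(FALSE, 12, 12)
  mask[2:4, 2:4] <- TRUE;  mask[2:4, 8:10] <- TRUE   # top row
  mask[8:10, 2:4] <- TRUE; mask[8:10, 8:10] <- TRUE  # bottom row
  lmap <- labelSeeds(mask, 5L)
  out <- assignClassesByRows(lmap, c(1L, 0L))
  expect_identical(seedClasses(out), c(1L, 1L, 0L, 0L))

  expect_error(assignClassesByRows(lmap, c(1L, 0L, 1L)), "layout mismatch")

  # synthetic plate with alternating rows: exact class counts
  sc <- renderScene(tinyScene(nRows = 4L, nCols = 5L))
  cl <- seedClasses(sc$truth)
  expect_equal(sum(cl == 1L), 10L)
  expect_equal(sum(cl == 0L), 10L)
  relabeled <- assignClassesByRows(
    labelSeeds(labelMatrix(sc$truth) > 0L, 5L), c(1L, 0L, 1L, 0L))
  expect_identical(seedClasses(relabeled), cl)
})

test_that("spectra extraction conserves foreground pixels and alignment", {
  sc <- renderScene(tinyScene())
  refl <- calibrateReflectance(sc$raw, sc$frames)
  tab <- extractSpectra(refl, sc$truth)
  expect_equal(nrow(spectraMatrix(tab)), sum(labelMatrix(sc$truth) > 0L))
  expect_equal(ncol(spectraMatrix(tab)), length(wavelengths(refl)))
  # class constant within seed and matching the truth
  for (id in unique(pixelSeedIds(tab)))
    expect_equal(unique(pixelClasses(tab)[pixelSeedIds(tab) == id]),
                 seedClasses(sc$truth)[id])

  # seeds of unknown class are excluded with a report
  lmap <- sc$truth
  cl <- seedClasses(lmap); cl[1] <- NA_integer_
  lmapNA <- new("SeedLabelMap", labels = labelMatrix(lmap), classes = cl)
  expect_message(tabNA <- extractSpectra(refl, lmapNA), "unknown")
  expect_equal(nrow(spectraMatrix(tabNA)),
               sum(labelMatrix(lmap) > 0L) - sum(labelMatrix(lmap) == 1L))
  expect_false(1L %in% pixelSeedIds(tabNA))

  # empty scene errors
  empty <- new("SeedLabelMap", labels = matrix(0L, 4, 4), classes = integer(0))
  small <- cropSpectral(refl, 1000, 1800)
  smallCube <- new("Hypercube", data = cubeData(small)[1:4, 1:4, , drop = FALSE],
                   wavelength = wavelengths(small), kind = "reflectance")
  expect_error(extractSpectra(smallCube, empty), "empty table")
})

test_that("seed-level split is stratified, reproducible and leak-free", {
  tab <- syntheticTable(nSeedsPerClass = 4, pixelsPerSeed = 7)
  sp <- splitBySeed(tab, 0.75, seed = 11)
  calSeeds <- unique(pixelSeedIds(sp$calibration))
  valSeeds <- unique(pixelSeedIds(sp$validation))
  expect_length(calSeeds, 6L)  # 3 per class
  expect_length(valSeeds, 2L)
  calClasses <- tapply(pixelClasses(sp$calibration),
                       pixelSeedIds(sp$calibration), function(v) v[1])
  expect_equal(sum(calClasses == 1), 3L)
  expect_length(intersect(calSeeds, valSeeds), 0L)

  # no seed straddles; union of rows equals the input
  expect_equal(nrow(spectraMatrix(sp$calibration)) +
                 nrow(spectraMatrix(sp$validation)), nrow(spectraMatrix(tab)))
  both <- rbind(cbind(pixelSeedIds(sp$calibration), spectraMatrix(sp$calibration)),
                cbind(pixelSeedIds(sp$validation), spectraMatrix(sp$validation)))
  orig <- cbind(pixelSeedIds(tab), spectraMatrix(tab))
  expect_equal(both[order(both[, 1]), ], orig[order(orig[, 1]), ],
               ignore_attr = TRUE)

  # determinism under the same seed
  sp2 <- splitBySeed(tab, 0.75, seed = 11)
  expect_identical(unique(pixelSeedIds(sp2$calibration)), calSeeds)

  # a class with < 2 seeds cannot be stratified
  one <- syntheticTable(nSeedsPerClass = 1)
  expect_error(splitBySeed(one, 0.75, 1), "stratify")
})

test_that("SpectraTable CSV round-trips", {
  tab <- syntheticTable(nSeedsPerClass = 2, pixelsPerSeed = 3, p = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  exportSpectraCSV(tab, path)
  back <- importSpectraCSV(path)
  expect_equal(spectraMatrix(back), spectraMatrix(tab), ignore_attr = TRUE)
  expect_identical(pixelClasses(back), pixelClasses(tab))
  expect_identical(pixelSeedIds(back), pixelSeedIds(tab))
  expect_equal(wavelengths(back), wavelengths(tab))
})
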