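#' Run the full seed-viability pipeline
#'
#' Chains every stage on one scene: reflectance calibration, spectral crop,
#' single-band masking, scan-line baseline correction, seed labeling and
#' row-layout class assignment, pretreatment, seed-stratified
#' calibration/validation split, cross-validated PLS-DA (full bands),
#' optionally VIP waveband selection and a refit on the selected bands, and
#' for each model the chemical image, per-seed detection rates, the ROC sweep
#' on the calibration seeds, the optimal detection rate, and seed-level
#' classification of both sets at that rate.
#'
#' The optimal detection rate is always learned on the calibration seeds only
#' and applied unchanged to the validation seeds.
#'
#' Exactly one input source must be given: a synthetic [SceneSpec-class]
#' (`scene`), or ENVI paths (`cubePath` + `whitePath` + `darkPath`) with a
#' `layout`.
#'
#' @param scene a [SceneSpec-class] (synthetic input source).
#' @param cubePath,whitePath,darkPath ENVI header paths (file input source);
#'   white/dark may be single-line reference cubes.
#' @param layout row-class layout for ground truth; defaults to the scene's.
#' @param pretreatment a [PretreatmentSpec-class] (default SNV).
#' @param maskBandNm segmentation band (default 1300 nm).
#' @param maskThreshold segmentation threshold; defaults to the synthetic
#'   scene's suggested contrast midpoint (required for file input).
#' @param seedsAbove mask polarity (see [thresholdMask()]).
#' @param minSeedPixels smallest kept seed component (default 20).
#' @param cropLo,cropHi spectral window in nm (default 1000-1800).
#' @param calibFraction seed-level calibration fraction (default 0.75).
#' @param cvFolds CV folds for latent-variable selection (default 10).
#' @param maxLV largest candidate latent-variable count (default 15).
#' @param vip run VIP selection and the few-band refit (default TRUE).
#' @param vipMaxBands optional cap on selected bands.
#' @param minSeparation minimum VIP peak separation in bands (default 2).
#' @param useOptimal classify at the ROC-optimal rate (TRUE, default) or at
#'   `fixedRate`.
#' @param fixedRate detection-rate threshold in percent when
#'   `useOptimal = FALSE` (default 50).
#' @param seed RNG seed for the split and CV folds.
#' @param outputDir if non-NULL, results (JSON summary, per-seed CSV, VIP CSV,
#'   color-coded PNG maps) are written here.
#' @param verbose log stage progress via `message()` (default FALSE).
#' @return a results list: `models` (full and, if selected, vip), each with
#'   the fitted [PLSDAModel-class], pixel accuracies, [ROCResult-class],
#'   applied `rate`, per-seed decisions and seed accuracies for both sets;
#'   plus `vip` (the [VIPResult-class]), `lmap`, `splitSeeds`, and the echoed
#'   parameters.
#' @export
runPipeline <- function(scene = NULL, cubePath = NULL, whitePath = NULL,
                        darkPath = NULL, layout = NULL,
                        pretreatment = pretreatmentSpec("snv"),
                        maskBandNm = 1300, maskThreshold = NULL,
                        seedsAbove = TRUE, minSeedPixels = 20L,
                        cropLo = 1000, cropHi = 1800,
                        calibFraction = 0.75, cvFolds = 10L, maxLV = 15L,
                        vip = TRUE, vipMaxBands = NULL, minSeparation = 2L,
                        useOptimal = TRUE, fixedRate = 50, seed = 1L,
                        outputDir = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message("[hyperseed] ", ...)
  fromScene <- !is.null(scene)
  fromFiles <- !is.null(cubePath)
  if (fromScene == fromFiles)
    stop("exactly one input source: scene XOR cubePath/whitePath/darkPath")

  if (fromScene) {
    stopifnot(is(scene, "SceneSpec"))
    say("rendering synthetic scene (seed ", scene@rngSeed, ")")
    sc <- renderScene(scene)
    raw <- sc$raw; frames <- sc$frames
    if (is.null(layout)) layout <- scene@classLayout
    if (is.null(maskThreshold)) maskThreshold <- sc$maskThreshold
  } else {
    if (is.null(whitePath) || is.null(darkPath))
      stop("file input needs cubePath, whitePath and darkPath")
    if (is.null(maskThreshold))
      stop("maskThreshold is required for file input")
    if (is.null(layout))
      stop("a row-class layout is required for file input")
    say("reading ENVI cubes")
    raw <- readENVI(cubePath)
    frameOf <- function(p) {
      cb <- readENVI(p)
      d <- dim(cb@data)
      if (d[1] == 1L) matrix(cb@data[1, , ], d[2], d[3]) else cb@data
    }
    frames <- new("CalibrationFrames", white = frameOf(whitePath),
                  dark = frameOf(darkPath))
  }

  say("calibrating reflectance")
  refl <- calibrateReflectance(raw, frames)
  refl <- cropSpectral(refl, cropLo, cropHi)
  say("cropped to ", length(refl@wavelength), " bands in ", cropLo, "-",
      cropHi, " nm")

  band <- bandImage(refl, maskBandNm)
  mask <- thresholdMask(band, maskThreshold, seedsAbove)
  say(sum(mask), " foreground pixels at the ", round(attr(band, "wavelength")),
      " nm band, threshold ", signif(maskThreshold, 3))
  refl <- baselineCorrect(refl, mask = mask)
  lmap <- labelSeeds(mask, minSeedPixels)
  lmap <- assignClassesByRows(lmap, layout)
  say(nSeeds(lmap), " seeds labeled")

  pre <- applyPretreatment(refl, pretreatment, mask)
  table <- extractSpectra(pre, lmap)
  split <- splitBySeed(table, calibFraction, seed)
  calSeeds <- sort(unique(split$calibration@seedId))
  say(length(calSeeds), " calibration / ",
      length(unique(split$validation@seedId)), " validation seeds")

  say("selecting latent variables (", cvFolds, "-fold CV, maxLV ", maxLV, ")")
  fullModel <- selectLatentVariables(split$calibration, maxLV = maxLV,
                                     nFolds = cvFolds, seed = seed)
  say("full-band model: A = ", nLatent(fullModel))

  vipRes <- NULL
  models <- list(full = fullModel)
  if (vip) {
    vipRes <- selectWavebands(vipScores(fullModel),
                              minSeparation = minSeparation,
                              maxBands = vipMaxBands)
    sel <- selectedBands(vipRes)
    say(length(sel), " VIP bands selected: ",
        paste(round(sel), collapse = ", "))
    if (length(sel) >= 1L)
      models$vip <- refitOnBands(split$calibration, sel, maxLV = maxLV,
                                 nFolds = cvFolds, seed = seed)
  }

  evalModel <- function(model) {
    pix <- lapply(split, function(tb) {
      pr <- predictPixels(model, tb)
      pixelAccuracy(pr$classes, tb@y)
    })
    chem <- chemicalImage(pre, lmap, model)
    rates <- detectionRates(chem, lmap)
    calRates <- rates[rates$seed_id %in% calSeeds, ]
    valRates <- rates[!rates$seed_id %in% calSeeds, ]
    roc <- rocCurve(calRates)
    rate <- if (useOptimal) optimalDetectionRate(roc) else fixedRate
    calDec <- classifySeeds(calRates, rate)
    valDec <- classifySeeds(valRates, rate)
    list(model = model,
         pixel = list(calibration = pix$calibration,
                      validation = pix$validation),
         roc = roc, rate = rate,
         decisions = list(calibration = calDec, validation = valDec),
         seedAcc = list(calibration = seedAccuracy(calDec),
                        validation = seedAccuracy(valDec)))
  }
  results <- lapply(models, evalModel)

  out <- list(models = results, vip = vipRes, lmap = lmap,
              splitSeeds = list(calibration = calSeeds),
              params = list(pretreatment = pretreatment@method,
                            maskBandNm = maskBandNm,
                            maskThreshold = maskThreshold,
                            cropLo = cropLo, cropHi = cropHi,
                            calibFraction = calibFraction,
                            cvFolds = cvFolds, maxLV = maxLV,
                            useOptimal = useOptimal, fixedRate = fixedRate,
                            seed = seed),
              version = "1")
  if (!is.null(outputDir)) writeBundle(out, outputDir)
  out
}

# results bundle: JSON summary + CSV tables + PNG maps
writeBundle <- function(out, outputDir) {
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(version = out$version, params = out$params)
  for (nm in names(out$models)) {
    r <- out$models[[nm]]
    summary[[nm]] <- list(
      n_latent = nLatent(r$model),
      bands = wavelengths(r$model),
      auc = rocAUC(r$roc),
      optimal_detection_rate = r$rate,
      pixel_accuracy = lapply(r$pixel, function(d)
        stats::setNames(as.list(d$accuracy_pct), d$group)),
      seed_accuracy = lapply(r$seedAcc, function(d)
        stats::setNames(as.list(d$accuracy_pct), d$group))
    )
    dec <- rbind(cbind(set = "calibration", r$decisions$calibration),
                 cbind(set = "validation", r$decisions$validation))
    utils::write.csv(dec, file.path(outputDir, paste0("seeds_", nm, ".csv")),
                     row.names = FALSE)
    renderResultMap(out$lmap,
                    rbind(r$decisions$calibration, r$decisions$validation),
                    file.path(outputDir, paste0("map_", nm, ".png")))
  }
  if (!is.null(out$vip))
    exportVIPCSV(out$vip, file.path(outputDir, "vip.csv"))
  jsonlite::write_json(summary, file.path(outputDir, "summary.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(outputDir)
}
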