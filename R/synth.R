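#' Construct a synthetic scene specification
#'
#' Defaults describe a small plate with an alternating-row class layout and
#' subtle class differences at three SWIR wavebands; see
#' [defaultPaperLikeScene()] for the full-size 10 x 10 plate.
#'
#' @param nRows,nCols seed grid dimensions.
#' @param seedRadius seed disk radius, pixels.
#' @param gap blank margin between/around seed cells, pixels (>= 1 so seeds
#'   never touch).
#' @param wavelength band axis in nm, strictly increasing.
#' @param classLayout one class per grid row, top first (1 viable,
#'   0 nonviable); default alternating starting viable.
#' @param deltaBands wavebands (nm) carrying the class difference.
#' @param deltaMagnitude amplitude (reflectance units) of the absorption-like
#'   bumps added to the nonviable class at `deltaBands`.
#' @param deltaWidth Gaussian sd of those bumps, nm.
#' @param scatterSD sd of per-pixel log multiplicative scatter.
#' @param driftSD sd of the per-scan-line additive baseline offset.
#' @param noiseSD sd of i.i.d. detector noise.
#' @param backgroundLevel flat background reflectance.
#' @param rngSeed reproducibility seed.
#' @return a [SceneSpec-class].
#' @export
sceneSpec <- function(nRows = 4L, nCols = 4L, seedRadius = 4L, gap = 4L,
                      wavelength = seq(1000, 2500, length.out = 256L),
                      classLayout = rep_len(c(1L, 0L), nRows),
                      deltaBands = c(1165, 1335, 1405),
                      deltaMagnitude = 0.014, deltaWidth = 20,
                      scatterSD = 0.08, driftSD = 0.012, noiseSD = 0.025,
                      backgroundLevel = 0.15, rngSeed = 1L) {
  new("SceneSpec", nRows = as.integer(nRows), nCols = as.integer(nCols),
      seedRadius = as.integer(seedRadius), gap = as.integer(gap),
      wavelength = as.numeric(wavelength),
      classLayout = as.integer(classLayout),
      deltaBands = as.numeric(deltaBands),
      deltaMagnitude = deltaMagnitude, deltaWidth = deltaWidth,
      scatterSD = scatterSD, driftSD = driftSD, noiseSD = noiseSD,
      backgroundLevel = backgroundLevel, rngSeed = as.integer(rngSeed))
}

#' The default full-size synthetic plate
#'
#' A 10 x 10 seed grid with rows alternating viable/nonviable (100 seeds, 50
#' per class) and 256 bands over 1000-2500 nm, matching a line-scan SWIR
#' detector's spectral resolution; downstream modeling crops to 1000-1800 nm.
#' Noise levels are moderate: with the default pipeline they place pixel-level
#' validation accuracy in the high-80s percent range, so that the value of
#' seed-level aggregation is visible.
#'
#' @param rngSeed reproducibility seed.
#' @return a [SceneSpec-class].
#' @export
defaultPaperLikeScene <- function(rngSeed = 1L) {
  sceneSpec(nRows = 10L, nCols = 10L, seedRadius = 4L, gap = 4L,
            rngSeed = rngSeed)
}

#' Synthetic soybean-like base reflectance spectrum
#'
#' Smooth deterministic curve with reflectance peaks near 1300 and 1600 nm
#' (fiber), valleys near 1200 and 1400 nm (protein/oil), a broad water
#' absorption past 1900 nm, and a gentle upward slope; values stay in (0, 1).
#'
#' @param wavelength numeric axis in nm.
#' @return numeric reflectance vector, same length as `wavelength`.
#' @export
baseSpectrum <- function(wavelength) {
  wl <- wavelength
  g <- function(center, sd) exp(-(wl - center)^2 / (2 * sd^2))
  0.42 + 8e-5 * (wl - 1000) +
    0.10 * g(1300, 55) + 0.08 * g(1600, 65) -
    0.08 * g(1200, 40) - 0.10 * g(1430, 45) -
    0.16 * g(1930, 70)
}

#' Mean spectrum of a seed class
#'
#' The viable class (1) is the base spectrum; the nonviable class (0) gains
#' Gaussian bumps of amplitude `deltaMagnitude` at `deltaBands` (aging-driven
#' composition change), so the class means differ only near those bands.
#'
#' @param spec a [SceneSpec-class].
#' @param cls 0 or 1.
#' @return numeric reflectance vector on the scene's axis.
#' @export
classSpectrum <- function(spec, cls) {
  stopifnot(is(spec, "SceneSpec"), cls %in% c(0L, 1L))
  s <- baseSpectrum(spec@wavelength)
  if (cls == 0L && length(spec@deltaBands) && spec@deltaMagnitude > 0) {
    for (b in spec@deltaBands)
      s <- s + spec@deltaMagnitude *
        exp(-(spec@wavelength - b)^2 / (2 * spec@deltaWidth^2))
  }
  s
}

#' Render a synthetic line-scan scene
#'
#' Rasterizes the seed grid as filled disks and synthesizes, per seed pixel,
#' `class spectrum x multiplicative scatter` (lognormal, per pixel), plus a
#' per-scan-line additive baseline offset (affecting the whole line,
#' background included -- this is what baseline correction estimates from the
#' background), plus i.i.d. detector noise everywhere. Raw counts and
#' white/dark frames are synthesized so that [calibrateReflectance()] recovers
#' the reflectance scene exactly. Fully reproducible from the spec's
#' `rngSeed`.
#'
#' @param spec a [SceneSpec-class].
#' @return list with `raw` ([Hypercube-class], kind `"raw"`),
#'   `frames` ([CalibrationFrames-class], single-line references),
#'   `truth` ([SeedLabelMap-class] with classes filled in), and
#'   `maskThreshold` (suggested 1300 nm segmentation threshold, the midpoint
#'   of the scene's seed/background contrast).
#' @export
renderScene <- function(spec) {
  stopifnot(is(spec, "SceneSpec"))
  validObject(spec)
  r <- spec@seedRadius; gap <- spec@gap
  cell <- 2L * r + gap
  nl <- spec@nRows * cell + gap
  ns <- spec@nCols * cell + gap
  nb <- length(spec@wavelength)

  # disk offsets
  off <- expand.grid(dl = -r:r, ds = -r:r)
  off <- off[off$dl^2 + off$ds^2 <= r^2, ]

  labels <- matrix(0L, nl, ns)
  classes <- integer(spec@nRows * spec@nCols)
  specs <- list(`0` = classSpectrum(spec, 0L), `1` = classSpectrum(spec, 1L))

  refl <- array(spec@backgroundLevel, dim = c(nl, ns, nb))
  withr::with_seed(spec@rngSeed, {
    id <- 0L
    for (i in seq_len(spec@nRows)) {
      cy <- gap + r + (i - 1L) * cell + 1L
      for (j in seq_len(spec@nCols)) {
        cx <- gap + r + (j - 1L) * cell + 1L
        id <- id + 1L
        cls <- spec@classLayout[i]
        classes[id] <- cls
        ll <- cy + off$dl; ss <- cx + off$ds
        labels[cbind(ll, ss)] <- id
        pixFlat <- (ss - 1L) * nl + ll
        factors <- exp(stats::rnorm(length(pixFlat), 0, spec@scatterSD))
        vals <- outer(factors, specs[[as.character(cls)]])
        idx <- rep(pixFlat, times = nb) +
          as.numeric(nl) * ns * rep(0:(nb - 1L), each = length(pixFlat))
        refl[idx] <- as.vector(vals)
      }
    }
    if (spec@driftSD > 0)
      refl <- refl + stats::rnorm(nl, 0, spec@driftSD)  # recycles over lines
    if (spec@noiseSD > 0)
      refl <- refl + array(stats::rnorm(length(refl), 0, spec@noiseSD),
                           dim = dim(refl))
  })

  # raw counts such that (raw - dark) / (white - dark) == refl exactly
  white <- outer(3500 + 300 * sin(seq(0, pi, length.out = ns)),
                 1 + 0.1 * sin(seq(0, 2 * pi, length.out = nb)))
  dark <- matrix(120, ns, nb)
  gain <- white - dark
  raw <- refl * aperm(array(gain, dim = c(ns, nb, nl)), c(3, 1, 2)) +
    aperm(array(dark, dim = c(ns, nb, nl)), c(3, 1, 2))

  seedAt1300 <- specs[["1"]][which.min(abs(spec@wavelength - 1300))]
  list(
    raw = new("Hypercube", data = raw, wavelength = spec@wavelength,
              kind = "raw"),
    frames = new("CalibrationFrames", white = white, dark = dark),
    truth = new("SeedLabelMap", labels = labels, classes = classes),
    maskThreshold = (spec@backgroundLevel + seedAt1300) / 2
  )
}

#' Write a synthetic scene to disk
#'
#' Renders the scene and writes the raw cube as ENVI, the white/dark frames
#' as single-line ENVI cubes, the ground-truth label map (PNG preview + JSON),
#' and the scene spec as JSON.
#'
#' @param spec a [SceneSpec-class] or path to a scene-spec JSON file.
#' @param outDir output directory (created if needed).
#' @return named character vector of the written header/file paths, invisibly.
#' @export
simulateScene <- function(spec, outDir) {
  if (is.character(spec)) spec <- sceneFromJSON(spec)
  stopifnot(is(spec, "SceneSpec"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  sc <- renderScene(spec)
  p <- c(cube = file.path(outDir, "cube.hdr"),
         white = file.path(outDir, "white.hdr"),
         dark = file.path(outDir, "dark.hdr"),
         truth = file.path(outDir, "truth.png"),
         spec = file.path(outDir, "scene.json"))
  writeENVI(sc$raw, p[["cube"]])
  asLine <- function(m) new("Hypercube",
                            data = array(m, dim = c(1L, nrow(m), ncol(m))),
                            wavelength = spec@wavelength, kind = "raw")
  writeENVI(asLine(sc$frames@white), p[["white"]])
  writeENVI(asLine(sc$frames@dark), p[["dark"]])
  writeLabelMap(sc$truth, p[["truth"]])
  sceneToJSON(spec, p[["spec"]])
  invisible(p)
}

#' Read / write a SceneSpec as JSON
#'
#' @param spec a [SceneSpec-class].
#' @param path JSON file path.
#' @return `sceneToJSON`: the path, invisibly; `sceneFromJSON`: a
#'   [SceneSpec-class]. Validation failures name the offending field.
#' @export
sceneToJSON <- function(spec, path) {
  stopifnot(is(spec, "SceneSpec"))
  fields <- slotNames("SceneSpec")
  jsonlite::write_json(stats::setNames(lapply(fields, slot, object = spec),
                                       fields),
                       path, digits = NA)
  invisible(path)
}

#' @rdname sceneToJSON
#' @export
sceneFromJSON <- function(path) {
  j <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                error = function(e) stop("cannot parse scene JSON: ",
                                         conditionMessage(e)))
  args <- j[intersect(names(j), names(formals(sceneSpec)))]
  do.call(sceneSpec, args)
}
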