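#' @import methods
NULL

#' Hypercube: a 3D hyperspectral image
#'
#' Container for a line-scan hyperspectral image: a 3D array with two spatial
#' dimensions (scan lines x samples along the line) and one spectral dimension,
#' plus the band-center wavelength axis in nanometres.
#'
#' @slot data numeric 3D array, `lines x samples x bands`.
#' @slot wavelength numeric vector of band-center wavelengths (nm), strictly
#'   increasing, one per band.
#' @slot kind character, one of `"raw"` (sensor counts), `"reflectance"`
#'   (calibrated, dimensionless) or `"preprocessed"` (after pretreatment).
#'   Reflectance values may slightly exceed \[0, 1\] from noise; no clipping is
#'   applied.
#'
#' @seealso [readENVI()], [calibrateReflectance()], [cropSpectral()]
#' @export
setClass("Hypercube",
  representation(data = "array", wavelength = "numeric", kind = "character"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@data)
    if (length(d) != 3L || any(d < 1L))
      msg <- c(msg, "data must be a 3D array with all dimensions >= 1")
    if (!all(is.finite(object@data)))
      msg <- c(msg, "data must be finite")
    wl <- object@wavelength
    if (length(d) == 3L && length(wl) != d[3L])
      msg <- c(msg, "wavelength length must equal the band dimension")
    if (!all(is.finite(wl)) || any(wl <= 0))
      msg <- c(msg, "wavelengths must be finite and positive")
    if (length(wl) > 1L && any(diff(wl) <= 0))
      msg <- c(msg, "wavelengths must be strictly increasing")
    if (length(object@kind) != 1L ||
        !object@kind %in% c("raw", "reflectance", "preprocessed"))
      msg <- c(msg, "kind must be one of 'raw', 'reflectance', 'preprocessed'")
    if (length(msg)) msg else TRUE
  }
)

#' CalibrationFrames: white-reference and dark-current frames
#'
#' White-reference (~99% reflectance panel) and dark-current (lens covered)
#' frames used for reflectance calibration. Each frame is either a
#' `samples x bands` matrix (a single reference scan line, broadcast across all
#' scan lines of the target cube, as line-scan systems record) or a full
#' `lines x samples x bands` array.
#'
#' @slot white numeric matrix or 3D array (counts).
#' @slot dark numeric matrix or 3D array, same shape contract as `white`.
#'
#' @seealso [calibrateReflectance()]
#' @export
setClass("CalibrationFrames",
  representation(white = "array", dark = "array"),
  validity = function(object) {
    msg <- character()
    for (nm in c("white", "dark")) {
      f <- slot(object, nm)
      if (!length(dim(f)) %in% c(2L, 3L))
        msg <- c(msg, sprintf("%s must be a matrix or 3D array", nm))
      if (!all(is.finite(f)))
        msg <- c(msg, sprintf("%s must be finite", nm))
    }
    if (!identical(dim(object@white), dim(object@dark)))
      msg <- c(msg, "white and dark must have identical dimensions")
    if (length(msg)) msg else TRUE
  }
)

#' SeedLabelMap: per-pixel seed identities and per-seed classes
#'
#' Integer label image assigning every pixel to a seed kernel (0 = background,
#' 1..K = seed IDs from 8-connected components in raster-scan order), together
#' with the per-seed ground-truth class where known.
#'
#' @slot labels integer matrix, `lines x samples`; values in 0..K with all IDs
#'   1..K present.
#' @slot classes integer vector of length K; 1 = viable, 0 = nonviable,
#'   `NA` = unknown. Element `i` is the class of seed ID `i`.
#'
#' @seealso [labelSeeds()], [assignClassesByRows()]
#' @export
setClass("SeedLabelMap",
  representation(labels = "matrix", classes = "integer"),
  validity = function(object) {
    msg <- character()
    lab <- object@labels
    if (!is.integer(lab)) msg <- c(msg, "labels must be an integer matrix")
    k <- max(0L, lab)
    ids <- sort(unique(lab[lab > 0L]))
    if (k > 0L && !identical(ids, seq_len(k)))
      msg <- c(msg, "seed IDs must be contiguous 1..K")
    if (length(object@classes) != k)
      msg <- c(msg, "classes must have one entry per seed ID")
    if (!all(object@classes %in% c(0L, 1L, NA_integer_)))
      msg <- c(msg, "classes must be 0, 1 or NA")
    if (length(msg)) msg else TRUE
  }
)

#' SpectraTable: per-pixel spectra with seed identity and class
#'
#' Flat table of foreground (seed) pixel spectra: one row per pixel in
#' raster-scan order, with the pixel's seed ID and the seed's class
#' (0 = nonviable, 1 = viable). Background pixels and seeds of unknown class
#' are never included.
#'
#' @slot X numeric matrix, `n_pixels x n_bands`.
#' @slot y integer vector of per-pixel class labels (constant within seed).
#' @slot seedId integer vector of per-pixel seed IDs.
#' @slot wavelength numeric vector of band wavelengths (nm) matching `ncol(X)`.
#'
#' @seealso [extractSpectra()], [splitBySeed()], [fitPLSDA()]
#' @export
setClass("SpectraTable",
  representation(X = "matrix", y = "integer", seedId = "integer",
                 wavelength = "numeric"),
  validity = function(object) {
    msg <- character()
    n <- nrow(object@X)
    if (length(object@y) != n || length(object@seedId) != n)
      msg <- c(msg, "X, y and seedId must have aligned rows")
    if (length(object@wavelength) != ncol(object@X))
      msg <- c(msg, "wavelength must match the number of columns of X")
    if (any(!object@y %in% c(0L, 1L)))
      msg <- c(msg, "y must be 0/1")
    if (n > 0L) {
      cls <- tapply(object@y, object@seedId, function(v) length(unique(v)))
      if (any(cls > 1L)) msg <- c(msg, "class must be constant within each seed")
    }
    if (length(msg)) msg else TRUE
  }
)

#' PretreatmentSpec: choice and parameters of a spectral pretreatment
#'
#' @slot method character; one of `"raw"`, `"snv"`, `"max"`, `"mean"`,
#'   `"range"`, `"smoothing"`.
#' @slot window odd integer >= 3, Savitzky-Golay window (smoothing only).
#' @slot polyorder integer >= 0 and < window, Savitzky-Golay polynomial order.
#'
#' @seealso [pretreatmentSpec()], [applyPretreatment()]
#' @export
setClass("PretreatmentSpec",
  representation(method = "character", window = "integer", polyorder = "integer"),
  prototype(method = "raw", window = 11L, polyorder = 2L),
  validity = function(object) {
    msg <- character()
    if (!object@method %in% c("raw", "snv", "max", "mean", "range", "smoothing"))
      msg <- c(msg, "method must be one of raw/snv/max/mean/range/smoothing")
    if (object@window < 3L || object@window %% 2L == 0L)
      msg <- c(msg, "window must be an odd integer >= 3")
    if (object@polyorder < 0L || object@polyorder >= object@window)
      msg <- c(msg, "polyorder must be >= 0 and < window")
    if (length(msg)) msg else TRUE
  }
)

#' PLSDAModel: a fitted NIPALS PLS-DA (PLS1) classifier
#'
#' Discriminant model regressing a 0/1 class dummy (1 = viable) on pixel
#' spectra by NIPALS partial least squares with X-side deflation. Prediction
#' for a raw (uncentered) spectrum x is `score = sum(x * beta) + b0`; the pixel
#' is called viable when the score strictly exceeds `threshold` (default 0.5).
#'
#' @slot nLV integer, number of latent variables A.
#' @slot W,P numeric matrices (`bands x A`): X-weights (unit columns) and
#'   X-loadings.
#' @slot scores numeric matrix (`n_train x A`): training scores T.
#' @slot q numeric vector (A): y-loadings.
#' @slot beta numeric vector (bands): regression coefficients on the raw
#'   spectrum scale.
#' @slot b0 numeric intercept.
#' @slot xMean,yMean centering constants from the training set.
#' @slot rmsecv numeric vector: cross-validated RMSE per candidate A
#'   (empty when the model was fitted at a fixed A).
#' @slot wavelength numeric vector (nm) naming the bands the model uses.
#' @slot threshold numeric pixel classification cut (0.5).
#'
#' @seealso [fitPLSDA()], [selectLatentVariables()], [predictPixels()],
#'   [vipScores()]
#' @export
setClass("PLSDAModel",
  representation(nLV = "integer", W = "matrix", P = "matrix",
                 scores = "matrix", q = "numeric", beta = "numeric",
                 b0 = "numeric", xMean = "numeric", yMean = "numeric",
                 rmsecv = "numeric", wavelength = "numeric",
                 threshold = "numeric"),
  prototype(threshold = 0.5),
  validity = function(object) {
    msg <- character()
    a <- object@nLV
    p <- length(object@beta)
    if (a < 1L) msg <- c(msg, "nLV must be >= 1")
    if (ncol(object@W) != a || ncol(object@P) != a || length(object@q) != a)
      msg <- c(msg, "W, P, q must have nLV components")
    if (nrow(object@W) != p || length(object@xMean) != p ||
        length(object@wavelength) != p)
      msg <- c(msg, "W, xMean, wavelength must match beta length")
    if (length(msg)) msg else TRUE
  }
)

#' VIPResult: variable importance in projection scores
#'
#' Per-wavelength VIP scores of a fitted PLS-DA model and the waveband subset
#' selected from them. The scores satisfy `mean(scores^2) == 1`; a score above
#' one marks an informative band.
#'
#' @slot scores numeric vector of VIP scores, one per model band.
#' @slot wavelength numeric vector (nm) aligned with `scores`.
#' @slot selected numeric vector of selected wavelengths (nm), subset of
#'   `wavelength`, each with score > 1.
#' @slot rule list recording the selection parameters (threshold, minimum peak
#'   separation, band cap).
#'
#' @seealso [vipScores()], [selectWavebands()]
#' @export
setClass("VIPResult",
  representation(scores = "numeric", wavelength = "numeric",
                 selected = "numeric", rule = "list"),
  validity = function(object) {
    msg <- character()
    if (length(object@scores) != length(object@wavelength))
      msg <- c(msg, "scores and wavelength must be aligned")
    if (length(object@scores) &&
        abs(mean(object@scores^2) - 1) > 1e-8)
      msg <- c(msg, "VIP scores must satisfy mean(scores^2) == 1")
    if (!all(object@selected %in% object@wavelength))
      msg <- c(msg, "selected wavelengths must lie on the axis")
    if (length(msg)) msg else TRUE
  }
)

#' ChemicalImage: per-pixel PLS-DA score map
#'
#' The 2D "chemical image" of a scene: the PLS-DA score of every foreground
#' pixel's pretreated spectrum, with background pixels set to `NA` (never 0,
#' which is a legal score), and its binarization at the 0.5 pixel cut
#' (strictly greater-than).
#'
#' @slot values numeric matrix of scores; `NA` on background.
#' @slot binary logical matrix, `values > 0.5` on foreground, `NA` on
#'   background.
#'
#' @seealso [chemicalImage()], [detectionRates()]
#' @export
setClass("ChemicalImage",
  representation(values = "matrix", binary = "matrix"),
  validity = function(object) {
    msg <- character()
    if (!identical(dim(object@values), dim(object@binary)))
      msg <- c(msg, "values and binary must have identical dimensions")
    if (!identical(is.na(object@values), is.na(object@binary)))
      msg <- c(msg, "values and binary must share the same background")
    if (length(msg)) msg else TRUE
  }
)

#' ROCResult: ROC analysis of per-seed detection rates
#'
#' ROC curve of the seed-level classifier "viable iff detection rate >=
#' threshold", swept over detection-rate thresholds (all integer percents 0-100
#' plus every observed rate; a final cut above 100 completes the curve at
#' sensitivity 0). Viable is the positive class throughout.
#'
#' @slot curve data.frame with columns `threshold`, `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity`.
#' @slot auc numeric in \[0, 1\]: trapezoidal area under sensitivity vs
#'   1 - specificity.
#' @slot optimalRate numeric percent: threshold minimizing FP + FN (ties:
#'   fewer FP, then the larger threshold).
#' @slot confusion named numeric (tp, fp, tn, fn) at `optimalRate`.
#'
#' @seealso [rocCurve()], [optimalDetectionRate()], [classifySeeds()]
#' @export
setClass("ROCResult",
  representation(curve = "data.frame", auc = "numeric",
                 optimalRate = "numeric", confusion = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@auc) && (object@auc < 0 || object@auc > 1))
      msg <- c(msg, "auc must be in [0, 1]")
    need <- c("threshold", "tp", "fp", "tn", "fn", "sensitivity", "specificity")
    if (!all(need %in% names(object@curve)))
      msg <- c(msg, "curve is missing required columns")
    if (length(msg)) msg else TRUE
  }
)

#' SceneSpec: parameters of a synthetic seed-plate scene
#'
#' Describes a synthetic line-scan SWIR scene of seed kernels on a plate:
#' grid geometry, wavelength axis, the row-wise class layout, the wavebands
#' carrying the (subtle) class difference, and the three distortions the
#' pipeline's corrections target -- per-pixel multiplicative scatter, per-scan-
#' line additive baseline drift, and i.i.d. detector noise.
#'
#' @slot nRows,nCols integer grid dimensions.
#' @slot seedRadius integer seed disk radius in pixels.
#' @slot gap integer blank margin between/around seed cells, pixels.
#' @slot wavelength numeric band axis (nm).
#' @slot classLayout integer vector, one class (1 viable / 0 nonviable) per
#'   grid row.
#' @slot deltaBands numeric wavebands (nm) where the nonviable class gains
#'   absorption-like Gaussian bumps.
#' @slot deltaMagnitude numeric bump amplitude (reflectance units).
#' @slot deltaWidth numeric bump Gaussian sd (nm).
#' @slot scatterSD numeric sd of log multiplicative per-pixel scatter.
#' @slot driftSD numeric sd of the per-scan-line additive offset.
#' @slot noiseSD numeric sd of i.i.d. detector noise.
#' @slot backgroundLevel numeric flat background reflectance.
#' @slot rngSeed integer reproducibility seed.
#'
#' @seealso [sceneSpec()], [renderScene()], [defaultPaperLikeScene()]
#' @export
setClass("SceneSpec",
  representation(nRows = "integer", nCols = "integer", seedRadius = "integer",
                 gap = "integer", wavelength = "numeric",
                 classLayout = "integer", deltaBands = "numeric",
                 deltaMagnitude = "numeric", deltaWidth = "numeric",
                 scatterSD = "numeric", driftSD = "numeric",
                 noiseSD = "numeric", backgroundLevel = "numeric",
                 rngSeed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@nRows < 1L || object@nCols < 1L)
      msg <- c(msg, "grid dimensions must be >= 1")
    if (object@seedRadius < 1L) msg <- c(msg, "seedRadius must be >= 1")
    if (object@gap < 1L)
      msg <- c(msg, "gap must be >= 1 so that seeds cannot overlap or touch")
    if (length(object@classLayout) != object@nRows)
      msg <- c(msg, "classLayout must have one class per grid row")
    if (!all(object@classLayout %in% c(0L, 1L)))
      msg <- c(msg, "classLayout entries must be 0 or 1")
    wl <- object@wavelength
    if (length(wl) < 2L || any(diff(wl) <= 0))
      msg <- c(msg, "wavelength must be strictly increasing, length >= 2")
    if (length(object@deltaBands) &&
        (min(object@deltaBands) < min(wl) || max(object@deltaBands) > max(wl)))
      msg <- c(msg, "deltaBands must lie within the wavelength range")
    sds <- c(object@scatterSD, object@driftSD, object@noiseSD)
    if (any(sds < 0)) msg <- c(msg, "noise standard deviations must be >= 0")
    if (object@deltaMagnitude < 0) msg <- c(msg, "deltaMagnitude must be >= 0")
    if (length(msg)) msg else TRUE
  }
)
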