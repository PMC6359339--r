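#' Band-center wavelengths of an object
#'
#' @param x a [Hypercube-class], [SpectraTable-class], [PLSDAModel-class],
#'   [VIPResult-class] or [SceneSpec-class].
#' @return numeric vector of wavelengths in nm.
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname wavelengths
#' @export
setMethod("wavelengths", "Hypercube", function(x) x@wavelength)
#' @rdname wavelengths
#' @export
setMethod("wavelengths", "SpectraTable", function(x) x@wavelength)
#' @rdname wavelengths
#' @export
setMethod("wavelengths", "PLSDAModel", function(x) x@wavelength)
#' @rdname wavelengths
#' @export
setMethod("wavelengths", "VIPResult", function(x) x@wavelength)
#' @rdname wavelengths
#' @export
setMethod("wavelengths", "SceneSpec", function(x) x@wavelength)

#' Raw data array of a Hypercube
#'
#' @param x a [Hypercube-class].
#' @return the `lines x samples x bands` array.
#' @export
setGeneric("cubeData", function(x) standardGeneric("cubeData"))
#' @rdname cubeData
#' @export
setMethod("cubeData", "Hypercube", function(x) x@data)

#' Processing state of a Hypercube
#'
#' @param x a [Hypercube-class].
#' @return `"raw"`, `"reflectance"` or `"preprocessed"`.
#' @export
setGeneric("cubeKind", function(x) standardGeneric("cubeKind"))
#' @rdname cubeKind
#' @export
setMethod("cubeKind", "Hypercube", function(x) x@kind)

#' @describeIn Hypercube dimensions of the data array.
#' @param x a `Hypercube`.
#' @export
setMethod("dim", "Hypercube", function(x) dim(x@data))

#' Number of labeled seeds
#'
#' @param x a [SeedLabelMap-class].
#' @return integer count K of seed kernels.
#' @export
setGeneric("nSeeds", function(x) standardGeneric("nSeeds"))
#' @rdname nSeeds
#' @export
setMethod("nSeeds", "SeedLabelMap", function(x) length(x@classes))

#' Label image of a SeedLabelMap
#'
#' @param x a [SeedLabelMap-class].
#' @return integer matrix of per-pixel seed IDs (0 = background).
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))
#' @rdname labelMatrix
#' @export
setMethod("labelMatrix", "SeedLabelMap", function(x) x@labels)

#' Per-seed classes of a SeedLabelMap
#'
#' @param x a [SeedLabelMap-class].
#' @return integer vector (1 = viable, 0 = nonviable, NA = unknown), element
#'   `i` for seed ID `i`.
#' @export
setGeneric("seedClasses", function(x) standardGeneric("seedClasses"))
#' @rdname seedClasses
#' @export
setMethod("seedClasses", "SeedLabelMap", function(x) x@classes)

#' Spectra matrix, labels and seed IDs of a SpectraTable
#'
#' @param x a [SpectraTable-class].
#' @return `spectraMatrix`: the `n_pixels x n_bands` matrix; `pixelClasses`:
#'   integer 0/1 labels; `pixelSeedIds`: integer seed IDs.
#' @export
setGeneric("spectraMatrix", function(x) standardGeneric("spectraMatrix"))
#' @rdname spectraMatrix
#' @export
setMethod("spectraMatrix", "SpectraTable", function(x) x@X)
#' @rdname spectraMatrix
#' @export
setGeneric("pixelClasses", function(x) standardGeneric("pixelClasses"))
#' @rdname spectraMatrix
#' @export
setMethod("pixelClasses", "SpectraTable", function(x) x@y)
#' @rdname spectraMatrix
#' @export
setGeneric("pixelSeedIds", function(x) standardGeneric("pixelSeedIds"))
#' @rdname spectraMatrix
#' @export
setMethod("pixelSeedIds", "SpectraTable", function(x) x@seedId)

#' @describeIn SpectraTable number of pixels and bands.
#' @param x a `SpectraTable`.
#' @export
setMethod("dim", "SpectraTable", function(x) dim(x@X))

#' Regression coefficients of a PLSDAModel
#'
#' @param x a [PLSDAModel-class].
#' @return `coefVector`: named numeric vector of beta coefficients (names are
#'   wavelengths in nm); `intercept`: the scalar intercept b0.
#' @export
setGeneric("coefVector", function(x) standardGeneric("coefVector"))
#' @rdname coefVector
#' @export
setMethod("coefVector", "PLSDAModel",
          function(x) stats::setNames(x@beta, format(x@wavelength)))
#' @rdname coefVector
#' @export
setGeneric("intercept", function(x) standardGeneric("intercept"))
#' @rdname coefVector
#' @export
setMethod("intercept", "PLSDAModel", function(x) x@b0)

#' Number of latent variables of a PLSDAModel
#'
#' @param x a [PLSDAModel-class].
#' @return integer A.
#' @export
setGeneric("nLatent", function(x) standardGeneric("nLatent"))
#' @rdname nLatent
#' @export
setMethod("nLatent", "PLSDAModel", function(x) x@nLV)

#' RMSECV curve of a PLSDAModel
#'
#' @param x a [PLSDAModel-class] fitted by [selectLatentVariables()].
#' @return numeric vector, cross-validated RMSE for A = 1..maxLV (empty if the
#'   model was fitted at a fixed A).
#' @export
setGeneric("rmsecvCurve", function(x) standardGeneric("rmsecvCurve"))
#' @rdname rmsecvCurve
#' @export
setMethod("rmsecvCurve", "PLSDAModel", function(x) x@rmsecv)

#' VIP scores and selected wavebands of a VIPResult
#'
#' @param x a [VIPResult-class].
#' @return `vipValues`: numeric VIP score per band; `selectedBands`: numeric
#'   vector of selected wavelengths (nm).
#' @export
setGeneric("vipValues", function(x) standardGeneric("vipValues"))
#' @rdname vipValues
#' @export
setMethod("vipValues", "VIPResult", function(x) x@scores)
#' @rdname vipValues
#' @export
setGeneric("selectedBands", function(x) standardGeneric("selectedBands"))
#' @rdname vipValues
#' @export
setMethod("selectedBands", "VIPResult", function(x) x@selected)

#' AUC and optimal threshold of an ROCResult
#'
#' @param x an [ROCResult-class].
#' @return `rocAUC`: area under the curve; `optimalRate`: the FP+FN-minimizing
#'   detection-rate threshold (percent); `rocTable`: the swept curve as a
#'   data.frame.
#' @export
setGeneric("rocAUC", function(x) standardGeneric("rocAUC"))
#' @rdname rocAUC
#' @export
setMethod("rocAUC", "ROCResult", function(x) x@auc)
#' @rdname rocAUC
#' @export
setGeneric("optimalRate", function(x) standardGeneric("optimalRate"))
#' @rdname rocAUC
#' @export
setMethod("optimalRate", "ROCResult", function(x) x@optimalRate)
#' @rdname rocAUC
#' @export
setGeneric("rocTable", function(x) standardGeneric("rocTable"))
#' @rdname rocAUC
#' @export
setMethod("rocTable", "ROCResult", function(x) x@curve)

setMethod("show", "Hypercube", function(object) {
  d <- dim(object@data)
  cat(sprintf("Hypercube (%s): %d lines x %d samples x %d bands, %.0f-%.0f nm\n",
              object@kind, d[1], d[2], d[3],
              min(object@wavelength), max(object@wavelength)))
})

setMethod("show", "SeedLabelMap", function(object) {
  cl <- object@classes
  cat(sprintf("SeedLabelMap: %d seeds on a %d x %d image (%d viable, %d nonviable, %d unknown)\n",
              length(cl), nrow(object@labels), ncol(object@labels),
              sum(cl == 1L, na.rm = TRUE), sum(cl == 0L, na.rm = TRUE),
              sum(is.na(cl))))
})

setMethod("show", "SpectraTable", function(object) {
  cat(sprintf("SpectraTable: %d pixel spectra x %d bands from %d seeds (%d viable / %d nonviable pixels)\n",
              nrow(object@X), ncol(object@X), length(unique(object@seedId)),
              sum(object@y == 1L), sum(object@y == 0L)))
})

setMethod("show", "PLSDAModel", function(object) {
  cat(sprintf("PLSDAModel: %d latent variable(s) on %d band(s) (%.0f-%.0f nm), b0 = %.4f\n",
              object@nLV, length(object@beta), min(object@wavelength),
              max(object@wavelength), object@b0))
  if (length(object@rmsecv))
    cat(sprintf("  RMSECV minimum %.4f at A = %d (curve over 1..%d)\n",
                min(object@rmsecv), which.min(object@rmsecv),
                length(object@rmsecv)))
})

setMethod("show", "VIPResult", function(object) {
  cat(sprintf("VIPResult: %d bands, %d above 1; selected: %s\n",
              length(object@scores), sum(object@scores > 1),
              if (length(object@selected))
                paste(round(object@selected), collapse = ", ") else "(none)"))
})

setMethod("show", "ChemicalImage", function(object) {
  fg <- !is.na(object@values)
  cat(sprintf("ChemicalImage: %d x %d, %d foreground pixels, %d detected (> 0.5)\n",
              nrow(object@values), ncol(object@values), sum(fg),
              sum(object@binary[fg])))
})

setMethod("show", "ROCResult", function(object) {
  cat(sprintf("ROCResult: AUC = %.4f, optimal detection rate = %.1f%% (FP=%d, FN=%d)\n",
              object@auc, object@optimalRate,
              object@confusion[["fp"]], object@confusion[["fn"]]))
})

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf("SceneSpec: %d x %d seed grid (radius %d px), %d bands %.0f-%.0f nm\n",
              object@nRows, object@nCols, object@seedRadius,
              length(object@wavelength), min(object@wavelength),
              max(object@wavelength)))
  cat(sprintf("  class delta %.3f at %s nm; scatter %.3f, drift %.3f, noise %.3f\n",
              object@deltaMagnitude,
              paste(round(object@deltaBands), collapse = "/"),
              object@scatterSD, object@driftSD, object@noiseSD))
})
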