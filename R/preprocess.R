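#' Construct a pretreatment specification
#'
#' @param method one of `"raw"`, `"snv"`, `"max"`, `"mean"`, `"range"`,
#'   `"smoothing"`.
#' @param window Savitzky-Golay window (odd, >= 3); used by `"smoothing"` only.
#' @param polyorder Savitzky-Golay polynomial order (>= 0, < window).
#' @return a [PretreatmentSpec-class].
#' @export
pretreatmentSpec <- function(method = c("raw", "snv", "max", "mean", "range",
                                        "smoothing"),
                             window = 11L, polyorder = 2L) {
  method <- match.arg(method)
  new("PretreatmentSpec", method = method, window = as.integer(window),
      polyorder = as.integer(polyorder))
}

#' Scan-line baseline correction
#'
#' Line-scan acquisition drifts in overall intensity from one scan line to the
#' next, producing striped band images. This correction estimates, for every
#' scan line and band, the additive offset as the median of that line's
#' background pixels, and subtracts it, flattening line-to-line shifts. A line
#' with no background pixels gets offset 0 (with a warning).
#'
#' The background/foreground split is taken from `mask` when supplied (TRUE =
#' seed); otherwise it is computed on the uncorrected cube by thresholding the
#' band image nearest `bandNm` (see [thresholdMask()]).
#'
#' @param cube a reflectance [Hypercube-class].
#' @param mask optional logical `lines x samples` matrix, TRUE on seeds.
#' @param bandNm reference wavelength for the internal mask (default 1300 nm).
#' @param threshold threshold for the internal mask; required if `mask` is
#'   missing.
#' @param seedsAbove direction of the internal mask comparison (see
#'   [thresholdMask()]).
#' @return the corrected [Hypercube-class] (same `kind`).
#' @export
baselineCorrect <- function(cube, mask = NULL, bandNm = 1300,
                            threshold = NULL, seedsAbove = TRUE) {
  stopifnot(is(cube, "Hypercube"))
  d <- dim(cube@data)
  if (is.null(mask)) {
    if (is.null(threshold))
      stop("either a mask or a threshold for the reference band is required")
    mask <- thresholdMask(bandImage(cube, bandNm), threshold, seedsAbove)
  }
  if (!identical(dim(mask), d[1:2]))
    stop("mask dimensions must match the cube's spatial dimensions")
  bg <- !mask
  data <- cube@data
  nEmpty <- 0L
  for (l in seq_len(d[1])) {
    idx <- which(bg[l, ])
    if (!length(idx)) { nEmpty <- nEmpty + 1L; next }
    # offset per band: median over this line's background samples
    offset <- apply(data[l, idx, , drop = FALSE], 3L, stats::median)
    data[l, , ] <- data[l, , ] - rep(offset, each = d[2])
  }
  if (nEmpty > 0L)
    warning(nEmpty, " scan line(s) had no background pixels; offset 0 used")
  new("Hypercube", data = data, wavelength = cube@wavelength, kind = cube@kind)
}

#' Standard normal variate (SNV) transform
#'
#' Centers a spectrum to mean 0 and scales to unit sample (n-1) standard
#' deviation, removing additive offsets and multiplicative scatter.
#'
#' @param spectrum numeric vector, length >= 2.
#' @return the transformed spectrum.
#' @export
snv <- function(spectrum) {
  if (length(spectrum) < 2L) stop("SNV needs a spectrum of length >= 2")
  s <- stats::sd(spectrum)
  if (!is.finite(s) || s == 0)
    stop("degenerate spectrum: zero standard deviation, SNV undefined")
  (spectrum - mean(spectrum)) / s
}

#' Max, mean or range normalization of a spectrum
#'
#' `max`: `x / max(x)`; `mean`: `x / mean(x)`; `range`:
#' `(x - min(x)) / (max(x) - min(x))`.
#'
#' @param spectrum numeric vector.
#' @param method `"max"`, `"mean"` or `"range"`.
#' @return the normalized spectrum.
#' @export
normalizeSpectrum <- function(spectrum, method = c("max", "mean", "range")) {
  method <- match.arg(method)
  switch(method,
    max = {
      m <- max(spectrum)
      if (m == 0) stop("degenerate spectrum: max is zero")
      spectrum / m
    },
    mean = {
      m <- mean(spectrum)
      if (m == 0) stop("degenerate spectrum: mean is zero")
      spectrum / m
    },
    range = {
      lo <- min(spectrum); hi <- max(spectrum)
      if (hi == lo) stop("degenerate spectrum: zero range")
      (spectrum - lo) / (hi - lo)
    })
}

#' Savitzky-Golay smoothing of a spectrum
#'
#' Least-squares polynomial smoothing over a sliding window
#' (`signal::sgolayfilt`); edges are handled by the polynomial fit within the
#' window, so polynomials of degree <= `polyorder` pass through unchanged.
#'
#' @param spectrum numeric vector.
#' @param window odd window length >= 3, `<= length(spectrum)`.
#' @param polyorder polynomial order, `< window`.
#' @return the smoothed spectrum, same length.
#' @export
smoothSpectrum <- function(spectrum, window = 11L, polyorder = 2L) {
  if (window > length(spectrum))
    stop("smoothing window (", window, ") exceeds spectrum length (",
         length(spectrum), ")")
  if (window < 3L || window %% 2L == 0L) stop("window must be odd and >= 3")
  if (polyorder < 0L || polyorder >= window)
    stop("polyorder must be >= 0 and < window")
  signal::sgolayfilt(spectrum, p = polyorder, n = window)
}

#' Apply a pretreatment to every foreground spectrum of a cube
#'
#' Applies the chosen pretreatment to each seed-pixel spectrum; background
#' pixels are left untouched (region-of-interest spectra are extracted before
#' preprocessing, so the background never enters the model). Per-spectrum
#' degeneracies (e.g. constant spectra under SNV) are collected and reported
#' as a single warning, with the offending pixels left untransformed.
#'
#' @param cube a [Hypercube-class].
#' @param spec a [PretreatmentSpec-class].
#' @param mask optional logical matrix, TRUE on seeds; if missing, every pixel
#'   is treated as foreground.
#' @return a [Hypercube-class] with `kind = "preprocessed"`.
#' @export
applyPretreatment <- function(cube, spec, mask = NULL) {
  stopifnot(is(cube, "Hypercube"), is(spec, "PretreatmentSpec"))
  validObject(spec)
  d <- dim(cube@data)
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  if (!identical(dim(mask), d[1:2]))
    stop("mask dimensions must match the cube's spatial dimensions")
  data <- cube@data
  if (spec@method != "raw" && any(mask)) {
    idx <- which(mask)  # column-major over lines x samples
    flat <- matrix(data, nrow = d[1] * d[2], ncol = d[3])
    spectra <- flat[idx, , drop = FALSE]
    fn <- switch(spec@method,
      snv = snv,
      max = function(x) normalizeSpectrum(x, "max"),
      mean = function(x) normalizeSpectrum(x, "mean"),
      range = function(x) normalizeSpectrum(x, "range"),
      smoothing = function(x) smoothSpectrum(x, spec@window, spec@polyorder))
    bad <- integer()
    for (i in seq_len(nrow(spectra))) {
      out <- tryCatch(fn(spectra[i, ]), error = function(e) NULL)
      if (is.null(out)) bad <- c(bad, idx[i]) else spectra[i, ] <- out
    }
    if (length(bad))
      warning(length(bad), " degenerate spectrum/spectra left untransformed ",
              "(flat pixel indices: ", paste(utils::head(bad, 10L),
                                             collapse = ", "),
              if (length(bad) > 10L) ", ..." else "", ")")
    flat[idx, ] <- spectra
    data <- array(flat, dim = d)
  }
  new("Hypercube", data = data, wavelength = cube@wavelength,
      kind = "preprocessed")
}
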