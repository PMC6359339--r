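#' Read an ENVI hypercube
#'
#' Reads an ENVI-format hyperspectral image: an ASCII `.hdr` header plus a flat
#' binary raster. Supported interleaves are BIL (band-interleaved-by-line) and
#' BSQ (band-sequential); the wavelength list must be present in the header.
#'
#' @param headerPath path to the `.hdr` file. The raster is looked up at the
#'   path named by a `data file` header entry if present, else at the header
#'   path with its extension replaced by `.dat` (or stripped).
#' @return a [Hypercube-class] with `kind = "raw"`.
#' @seealso [writeENVI()]
#' @export
readENVI <- function(headerPath) {
  if (!file.exists(headerPath))
    stop("ENVI header not found: ", headerPath)
  hdr <- parseEnviHeader(headerPath)
  for (k in c("samples", "lines", "bands", "interleave", "data type"))
    if (is.null(hdr[[k]]))
      stop("ENVI header is missing required field '", k, "'")
  if (is.null(hdr[["wavelength"]]))
    stop("ENVI header has no wavelength metadata; a wavelength list is required")
  interleave <- tolower(hdr[["interleave"]])
  if (!interleave %in% c("bil", "bsq"))
    stop("unsupported ENVI interleave '", interleave, "' (only BIL and BSQ)")
  dtype <- as.integer(hdr[["data type"]])
  if (!dtype %in% c(4L, 5L))
    stop("unsupported ENVI data type ", dtype, " (only 4 = float32, 5 = float64)")
  nl <- as.integer(hdr[["lines"]]); ns <- as.integer(hdr[["samples"]])
  nb <- as.integer(hdr[["bands"]])
  wl <- as.numeric(strsplit(gsub("[{}]", "", hdr[["wavelength"]]), ",")[[1]])
  if (length(wl) != nb)
    stop("header declares ", nb, " bands but lists ", length(wl), " wavelengths")

  rasterPath <- hdr[["data file"]]
  if (is.null(rasterPath)) {
    rasterPath <- sub("\\.hdr$", ".dat", headerPath, ignore.case = TRUE)
    if (!file.exists(rasterPath))
      rasterPath <- sub("\\.hdr$", "", headerPath, ignore.case = TRUE)
  }
  if (!file.exists(rasterPath))
    stop("ENVI raster file not found for header ", headerPath)

  size <- if (dtype == 4L) 4L else 8L
  n <- nl * ns * nb
  vals <- readBin(rasterPath, "double", n = n + 1L, size = size, endian = "little")
  if (length(vals) != n)
    stop("raster holds ", length(vals), " values but header implies ", n,
         " (", nl, " lines x ", ns, " samples x ", nb, " bands)")
  data <- if (interleave == "bil") {
    aperm(array(vals, dim = c(ns, nb, nl)), c(3, 1, 2))
  } else {
    aperm(array(vals, dim = c(ns, nl, nb)), c(2, 1, 3))
  }
  new("Hypercube", data = data, wavelength = wl, kind = "raw")
}

#' Write an ENVI hypercube
#'
#' Writes an ASCII ENVI header and binary raster. The raster is stored as
#' 32-bit little-endian floats by default; the wavelength axis is written to
#' the header at full precision.
#'
#' @param cube a [Hypercube-class].
#' @param headerPath destination `.hdr` path; the raster is written next to it
#'   with the `.dat` extension.
#' @param interleave `"bil"` or `"bsq"`.
#' @param dtype 4 (float32, default) or 5 (float64).
#' @return the header path, invisibly.
#' @export
writeENVI <- function(cube, headerPath, interleave = c("bil", "bsq"), dtype = 4L) {
  stopifnot(is(cube, "Hypercube"))
  validObject(cube)
  interleave <- match.arg(interleave)
  if (!dtype %in% c(4L, 5L)) stop("dtype must be 4 (float32) or 5 (float64)")
  d <- dim(cube@data)
  rasterPath <- sub("\\.hdr$", ".dat", headerPath, ignore.case = TRUE)
  if (identical(rasterPath, headerPath)) rasterPath <- paste0(headerPath, ".dat")

  hdr <- c(
    "ENVI",
    "description = { hyperseed hypercube }",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", dtype),
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    sprintf("data file = %s", rasterPath),
    sprintf("wavelength units = Nanometers"),
    sprintf("wavelength = { %s }",
            paste(format(cube@wavelength, digits = 17, trim = TRUE),
                  collapse = ", "))
  )
  ok <- tryCatch({
    writeLines(hdr, headerPath)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write ENVI header to ", headerPath)

  vals <- if (interleave == "bil") {
    as.vector(aperm(cube@data, c(2, 3, 1)))
  } else {
    as.vector(aperm(cube@data, c(2, 1, 3)))
  }
  con <- file(rasterPath, "wb")
  on.exit(close(con))
  writeBin(vals, con, size = if (dtype == 4L) 4L else 8L, endian = "little")
  invisible(headerPath)
}

parseEnviHeader <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (!length(txt) || !grepl("^ENVI", txt[1]))
    stop("not an ENVI header (missing ENVI magic line): ", path)
  # join continued { ... } values spanning multiple lines
  joined <- character(); buf <- ""
  for (ln in txt[-1]) {
    buf <- if (nzchar(buf)) paste(buf, ln) else ln
    nOpen <- lengths(regmatches(buf, gregexpr("\\{", buf)))
    nClose <- lengths(regmatches(buf, gregexpr("\\}", buf)))
    if (nOpen == nClose) { joined <- c(joined, buf); buf <- "" }
  }
  hdr <- list()
  for (ln in joined) {
    m <- regmatches(ln, regexec("^\\s*([^=]+?)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(m) == 3L) hdr[[tolower(m[2])]] <- trimws(m[3])
  }
  hdr
}

#' Reflectance calibration from white and dark frames
#'
#' Converts raw counts to reflectance per element:
#' `R = (raw - dark) / (white - dark)`. Denominator entries with magnitude
#' below `floorGuard` (dead detector pixels) are floored to `floorGuard` and
#' counted in a warning. Reference frames given as a single `samples x bands`
#' line are broadcast across all scan lines.
#'
#' @param raw a [Hypercube-class] with `kind = "raw"`.
#' @param frames a [CalibrationFrames-class].
#' @param floorGuard positive floor for the denominator (default 1e-9).
#' @return a [Hypercube-class] with `kind = "reflectance"`. No clipping to
#'   \[0, 1\] is applied.
#' @export
calibrateReflectance <- function(raw, frames, floorGuard = 1e-9) {
  stopifnot(is(raw, "Hypercube"), is(frames, "CalibrationFrames"))
  if (raw@kind != "raw")
    stop("calibrateReflectance expects a raw-count cube (kind = 'raw')")
  d <- dim(raw@data)
  white <- broadcastFrame(frames@white, d, "white")
  dark <- broadcastFrame(frames@dark, d, "dark")
  denom <- white - dark
  nGuard <- sum(abs(denom) < floorGuard)
  if (nGuard > 0L) {
    warning(nGuard, " white-minus-dark element(s) below ", floorGuard,
            " floored (dead detector pixels?)")
    denom[abs(denom) < floorGuard] <- floorGuard
  }
  new("Hypercube", data = (raw@data - dark) / denom,
      wavelength = raw@wavelength, kind = "reflectance")
}

broadcastFrame <- function(f, d, what) {
  fd <- dim(f)
  if (length(fd) == 3L) {
    if (!identical(fd, d))
      stop(what, " frame dimensions ", paste(fd, collapse = "x"),
           " do not match cube ", paste(d, collapse = "x"))
    return(f)
  }
  if (!identical(fd, d[2:3]))
    stop(what, " frame must be samples x bands (", d[2], " x ", d[3],
         "); got ", paste(fd, collapse = " x "))
  aperm(array(f, dim = c(d[2], d[3], d[1])), c(3, 1, 2))
}

#' Crop a hypercube to a wavelength window
#'
#' Retains bands with `loNm <= wavelength <= hiNm` (inclusive on both ends).
#'
#' @param cube a [Hypercube-class].
#' @param loNm,hiNm window bounds in nm, `loNm < hiNm`.
#' @return the cropped [Hypercube-class].
#' @export
cropSpectral <- function(cube, loNm, hiNm) {
  stopifnot(is(cube, "Hypercube"))
  if (loNm >= hiNm) stop("loNm must be < hiNm")
  keep <- cube@wavelength >= loNm & cube@wavelength <= hiNm
  if (!any(keep))
    stop("empty spectral range: no bands between ", loNm, " and ", hiNm, " nm")
  new("Hypercube", data = cube@data[, , keep, drop = FALSE],
      wavelength = cube@wavelength[keep], kind = cube@kind)
}

#' Extract the single-band image nearest a target wavelength
#'
#' Returns the 2D slice at the band whose center is nearest `targetNm`;
#' equidistant ties resolve to the lower wavelength. The chosen band's actual
#' wavelength is attached as attribute `"wavelength"`.
#'
#' @param cube a [Hypercube-class].
#' @param targetNm target wavelength in nm.
#' @return `lines x samples` numeric matrix with attribute `"wavelength"`.
#' @export
bandImage <- function(cube, targetNm) {
  stopifnot(is(cube, "Hypercube"))
  wl <- cube@wavelength
  if (!length(wl)) stop("empty wavelength axis")
  dist <- abs(wl - targetNm)
  idx <- which(dist == min(dist))[1L]  # tie -> lower wavelength (axis increasing)
  img <- cube@data[, , idx]
  attr(img, "wavelength") <- wl[idx]
  img
}
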