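#' Threshold a band image into a seed/background mask
#'
#' "Simple threshold" segmentation on a single-band image (conventionally the
#' band nearest 1300 nm, where seed/background contrast is strong). The
#' comparison direction is configurable because the contrast direction depends
#' on the plate: by default pixels above the threshold are seeds.
#'
#' @param band numeric `lines x samples` matrix.
#' @param threshold numeric cut.
#' @param seedsAbove if TRUE (default), `band > threshold` marks seeds;
#'   if FALSE, `band < threshold`.
#' @return logical matrix, TRUE on seeds.
#' @export
thresholdMask <- function(band, threshold, seedsAbove = TRUE) {
  if (!all(is.finite(band))) stop("band image must be finite")
  if (seedsAbove) band > threshold else band < threshold
}

#' Label connected seed kernels in a mask
#'
#' 8-connected component labeling (diagonal contact joins components).
#' Components smaller than `minSeedPixels` are removed as debris. Seed IDs are
#' assigned contiguously 1..K in raster-scan order of each component's first
#' pixel.
#'
#' @param mask logical `lines x samples` matrix, TRUE on seeds.
#' @param minSeedPixels minimum component size kept (default 20).
#' @return a [SeedLabelMap-class] with all classes unknown (`NA`).
#' @export
labelSeeds <- function(mask, minSeedPixels = 20L) {
  stopifnot(is.matrix(mask), is.logical(mask))
  lab <- label8(mask)
  if (max(lab) > 0L) {
    sizes <- tabulate(lab[lab > 0L])
    drop <- which(sizes < minSeedPixels)
    if (length(drop)) lab[lab %in% drop] <- 0L
  }
  ids <- rasterOrderIds(lab)
  if (!length(ids))
    stop("empty scene: no seed component of at least ", minSeedPixels,
         " pixels")
  relab <- integer(max(lab))
  relab[ids] <- seq_along(ids)
  lab[lab > 0L] <- relab[lab[lab > 0L]]
  new("SeedLabelMap", labels = lab,
      classes = rep(NA_integer_, length(ids)))
}

# Two-pass union-find 8-connected labeling; raster scan = lines outer,
# samples inner.
label8 <- function(mask) {
  nl <- nrow(mask); ns <- ncol(mask)
  lab <- matrix(0L, nl, ns)
  parent <- integer(0)
  findRoot <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  nextId <- 0L
  for (l in seq_len(nl)) {
    for (s in seq_len(ns)) {
      if (!mask[l, s]) next
      nb <- integer(0)
      if (l > 1L) {
        if (s > 1L && lab[l - 1L, s - 1L]) nb <- c(nb, lab[l - 1L, s - 1L])
        if (lab[l - 1L, s]) nb <- c(nb, lab[l - 1L, s])
        if (s < ns && lab[l - 1L, s + 1L]) nb <- c(nb, lab[l - 1L, s + 1L])
      }
      if (s > 1L && lab[l, s - 1L]) nb <- c(nb, lab[l, s - 1L])
      if (!length(nb)) {
        nextId <- nextId + 1L
        parent[nextId] <- nextId
        lab[l, s] <- nextId
      } else {
        roots <- vapply(unique(nb), findRoot, integer(1))
        r <- min(roots)
        lab[l, s] <- r
        for (o in roots) parent[o] <- r
      }
    }
  }
  if (nextId > 0L) {
    roots <- vapply(seq_len(nextId), findRoot, integer(1))
    lab[lab > 0L] <- roots[lab[lab > 0L]]
  }
  lab
}

# component IDs in raster-scan order of first pixel
rasterOrderIds <- function(lab) {
  v <- as.vector(t(lab))
  unique(v[v > 0L])
}

#' Assign ground-truth classes to seeds from a plate row layout
#'
#' Seeds on the plate sit in a grid whose rows alternate between viable and
#' nonviable. Each seed's centroid vertical (scan-line) coordinate is binned
#' into `length(layout)` equal intervals spanning the centroid range; the
#' seed inherits the class of its row. Centroids falling within
#' `guardMargin` bin-widths of an interior bin boundary are flagged unknown
#' (`NA`).
#'
#' @param lmap a [SeedLabelMap-class].
#' @param layout integer vector, one class per grid row (1 = viable,
#'   0 = nonviable), top row first.
#' @param guardMargin ambiguity margin as a fraction of the bin width
#'   (default 0.05).
#' @return the [SeedLabelMap-class] with classes filled in.
#' @export
assignClassesByRows <- function(lmap, layout, guardMargin = 0.05) {
  stopifnot(is(lmap, "SeedLabelMap"))
  layout <- as.integer(layout)
  if (!all(layout %in% c(0L, 1L))) stop("layout entries must be 0 or 1")
  k <- nSeeds(lmap)
  lab <- lmap@labels
  cy <- vapply(seq_len(k), function(id) mean(which(lab == id, arr.ind = TRUE)[, 1]),
               numeric(1))
  L <- length(layout)
  lo <- min(cy); hi <- max(cy)
  if (L > 1L && hi == lo)
    stop("layout mismatch: ", L, " rows declared but all seed centroids ",
         "fall on one row")
  eps <- max(hi - lo, 1) * 1e-9
  breaks <- seq(lo - eps, hi + eps, length.out = L + 1L)
  bin <- findInterval(cy, breaks, rightmost.closed = TRUE)
  if (L > 1L && !all(seq_len(L) %in% bin))
    stop("layout mismatch: ", L, " rows declared but only ",
         length(unique(bin)), " occupied; empty grid row(s) detected")
  classes <- layout[bin]
  if (L > 1L) {
    w <- diff(breaks)[1]
    inner <- breaks[-c(1L, L + 1L)]
    ambiguous <- vapply(cy, function(y) any(abs(y - inner) < guardMargin * w),
                        logical(1))
    if (any(ambiguous)) {
      warning(sum(ambiguous), " seed(s) with centroid within the guard margin",
              " of a row boundary flagged unknown")
      classes[ambiguous] <- NA_integer_
    }
  }
  new("SeedLabelMap", labels = lab, classes = as.integer(classes))
}

#' Extract per-pixel seed spectra from a labeled cube
#'
#' One row per foreground pixel, in raster-scan order, carrying the pixel's
#' spectrum, seed ID and the seed's class. Seeds with unknown class are
#' excluded (count reported).
#'
#' @param cube a [Hypercube-class].
#' @param lmap a [SeedLabelMap-class] with classes assigned, same spatial
#'   shape as the cube.
#' @return a [SpectraTable-class].
#' @export
extractSpectra <- function(cube, lmap) {
  stopifnot(is(cube, "Hypercube"), is(lmap, "SeedLabelMap"))
  d <- dim(cube@data)
  if (!identical(dim(lmap@labels), d[1:2]))
    stop("cube and label map spatial dimensions differ")
  classes <- lmap@classes
  nUnknown <- sum(is.na(classes))
  if (nUnknown > 0L)
    message(nUnknown, " seed(s) of unknown class excluded from the table")
  keepSeed <- which(!is.na(classes))
  lab <- lmap@labels
  flatLab <- as.vector(lab)
  # raster-scan order: lines outer, samples inner
  lineOf <- rep(seq_len(d[1]), times = d[2])
  sampOf <- rep(seq_len(d[2]), each = d[1])
  sel <- which(flatLab > 0L & flatLab %in% keepSeed)
  if (!length(sel)) stop("empty table: no labeled foreground pixels remain")
  sel <- sel[order(lineOf[sel], sampOf[sel])]
  flat <- matrix(cube@data, nrow = d[1] * d[2], ncol = d[3])
  X <- flat[sel, , drop = FALSE]
  sid <- flatLab[sel]
  new("SpectraTable", X = X, y = classes[sid], seedId = sid,
      wavelength = cube@wavelength)
}

#' Split a spectra table into calibration and validation sets by seed
#'
#' The split is stratified by class at the seed level: all pixels of a seed
#' land in the same subset, preventing pixel leakage between sets. Per class,
#' `round(calibFraction * n_seeds)` seeds go to calibration.
#'
#' @param table a [SpectraTable-class].
#' @param calibFraction fraction of seeds per class in the calibration set
#'   (default 0.75).
#' @param seed integer RNG seed; the same seed reproduces the same split.
#' @return list with elements `calibration` and `validation`, both
#'   [SpectraTable-class].
#' @export
splitBySeed <- function(table, calibFraction = 0.75, seed = 1L) {
  stopifnot(is(table, "SpectraTable"))
  if (calibFraction <= 0 || calibFraction >= 1)
    stop("calibFraction must be in (0, 1)")
  seedClass <- tapply(table@y, table@seedId, function(v) v[1])
  ids <- as.integer(names(seedClass))
  calibIds <- integer(0)
  withr::with_seed(seed, {
    for (cl in c(0L, 1L)) {
      clIds <- ids[seedClass == cl]
      if (length(clIds) < 2L)
        stop("cannot stratify: class ", cl, " has fewer than 2 seeds")
      nCal <- round(calibFraction * length(clIds))
      nCal <- min(max(nCal, 1L), length(clIds) - 1L)
      calibIds <- c(calibIds, sample(clIds, nCal))
    }
  })
  inCal <- table@seedId %in% calibIds
  list(calibration = subsetTable(table, inCal),
       validation = subsetTable(table, !inCal))
}

subsetTable <- function(table, keep) {
  new("SpectraTable", X = table@X[keep, , drop = FALSE],
      y = table@y[keep], seedId = table@seedId[keep],
      wavelength = table@wavelength)
}

#' Export / import a SpectraTable as CSV
#'
#' Columns: `seed_id`, `class`, then one column per wavelength (header
#' `nm<value>`).
#'
#' @param table a [SpectraTable-class].
#' @param path destination CSV path.
#' @return `exportSpectraCSV`: the path, invisibly. `importSpectraCSV`: a
#'   [SpectraTable-class].
#' @export
exportSpectraCSV <- function(table, path) {
  stopifnot(is(table, "SpectraTable"))
  df <- data.frame(seed_id = table@seedId, class = table@y, table@X)
  names(df)[-(1:2)] <- paste0("nm", format(table@wavelength, trim = TRUE,
                                           digits = 15))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname exportSpectraCSV
#' @export
importSpectraCSV <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  wlCols <- grep("^nm", names(df))
  new("SpectraTable",
      X = as.matrix(df[, wlCols, drop = FALSE]),
      y = as.integer(df$class), seedId = as.integer(df$seed_id),
      wavelength = as.numeric(sub("^nm", "", names(df)[wlCols])))
}

#' Write a SeedLabelMap to disk
#'
#' Writes a grayscale PNG preview of the label image (labels scaled to the
#' full intensity range) and a JSON sidecar holding the exact label matrix
#' and the per-seed class map.
#'
#' @param lmap a [SeedLabelMap-class].
#' @param pngPath destination PNG path.
#' @param jsonPath destination JSON path (default: PNG path with `.json`).
#' @return the JSON path, invisibly.
#' @export
writeLabelMap <- function(lmap, pngPath,
                          jsonPath = sub("\\.png$", ".json", pngPath)) {
  stopifnot(is(lmap, "SeedLabelMap"))
  k <- max(1L, nSeeds(lmap))
  png::writePNG(lmap@labels / k, pngPath)
  jsonlite::write_json(
    list(labels = lmap@labels, classes = lmap@classes),
    jsonPath, digits = NA, na = "null")
  invisible(jsonPath)
}
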