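#' Chemical image: per-pixel PLS-DA scores over a scene
#'
#' Applies the model's beta coefficients to every foreground (seed) pixel of
#' the pretreated cube, producing the 2D score map, and binarizes it at the
#' model's 0.5 pixel cut (strict greater-than). Background is eliminated
#' before thresholding and carried as `NA` (0 is a legal score, so it is never
#' used as a sentinel). The model may use a band subset; its wavelengths are
#' looked up on the cube's axis.
#'
#' @param cube a pretreated [Hypercube-class].
#' @param lmap a [SeedLabelMap-class], same spatial shape.
#' @param model a [PLSDAModel-class].
#' @return a [ChemicalImage-class].
#' @export
chemicalImage <- function(cube, lmap, model) {
  stopifnot(is(cube, "Hypercube"), is(lmap, "SeedLabelMap"),
            is(model, "PLSDAModel"))
  d <- dim(cube@data)
  if (!identical(dim(lmap@labels), d[1:2]))
    stop("cube and label map spatial dimensions differ")
  idx <- vapply(model@wavelength, function(nm) {
    j <- which(abs(cube@wavelength - nm) < 1e-6)
    if (!length(j))
      stop("model band ", nm, " nm is not on the cube's axis")
    j[1]
  }, integer(1))
  fg <- which(as.vector(lmap@labels) > 0L)
  flat <- matrix(cube@data, nrow = d[1] * d[2], ncol = d[3])
  scores <- as.numeric(flat[fg, idx, drop = FALSE] %*% model@beta) + model@b0
  values <- matrix(NA_real_, d[1], d[2])
  values[fg] <- scores
  binary <- matrix(NA, d[1], d[2])
  binary[fg] <- scores > model@threshold
  new("ChemicalImage", values = values, binary = binary)
}

#' Per-seed pixel detection rates
#'
#' For each seed kernel, counts its detected pixels (chemical-image score
#' above 0.5) and computes the detection rate
#' `100 * n_detected / n_total` percent.
#'
#' @param chem a [ChemicalImage-class].
#' @param lmap a [SeedLabelMap-class], same spatial shape.
#' @return a seed-decision data.frame with one row per seed: `seed_id`,
#'   `n_total`, `n_detected`, `detection_pct`, `predicted_class` (`NA` until
#'   [classifySeeds()]), `true_class`.
#' @export
detectionRates <- function(chem, lmap) {
  stopifnot(is(chem, "ChemicalImage"), is(lmap, "SeedLabelMap"))
  if (!identical(dim(chem@values), dim(lmap@labels)))
    stop("chemical image and label map dimensions differ")
  k <- nSeeds(lmap)
  lab <- as.vector(lmap@labels)
  det <- as.vector(chem@binary)
  nTotal <- tabulate(lab[lab > 0L], nbins = k)
  nDet <- tabulate(lab[lab > 0L & !is.na(det) & det], nbins = k)
  data.frame(
    seed_id = seq_len(k),
    n_total = nTotal,
    n_detected = nDet,
    detection_pct = 100 * nDet / nTotal,
    predicted_class = NA_integer_,
    true_class = lmap@classes
  )
}

#' Classify seeds at a detection-rate threshold
#'
#' A seed is viable iff its detection rate is greater than or equal to the
#' threshold (inclusive on the seed rule; the pixel rule underneath is
#' strict).
#'
#' @param rates a seed-decision data.frame from [detectionRates()].
#' @param detectionRate threshold in percent, 0..100.
#' @return the data.frame with `predicted_class` filled in.
#' @export
classifySeeds <- function(rates, detectionRate) {
  if (detectionRate < 0 || detectionRate > 100)
    stop("detectionRate must be in [0, 100]")
  rates$predicted_class <- as.integer(rates$detection_pct >= detectionRate)
  rates
}

#' ROC curve over detection-rate thresholds
#'
#' Sweeps the seed-level rule "viable iff detection rate >= t" over every
#' integer percent 0..100 plus every observed detection rate (so each distinct
#' confusion matrix is realized exactly), with a final cut above 100 closing
#' the curve at sensitivity 0. Viable is the positive class:
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)`. AUC is the
#' trapezoidal area under sensitivity vs 1 - specificity; the optimal rate
#' minimizes FP + FN (ties: fewer FP, then the larger threshold), searched
#' over thresholds in \[0, 100\].
#'
#' @param rates a seed-decision data.frame with `true_class` present for both
#'   classes.
#' @return an [ROCResult-class].
#' @export
rocCurve <- function(rates) {
  truth <- rates$true_class
  if (any(is.na(truth))) stop("all seeds need a known true class for ROC")
  n1 <- sum(truth == 1L); n0 <- sum(truth == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("undefined ROC: both true classes must be present")
  dp <- rates$detection_pct
  grid <- sort(unique(c(0:100, dp)))
  thresholds <- c(grid, Inf)  # Inf: cut above every rate -> (0, 0) endpoint
  tp <- fp <- tn <- fn <- integer(length(thresholds))
  for (i in seq_along(thresholds)) {
    pred <- dp >= thresholds[i]
    tp[i] <- sum(pred & truth == 1L)
    fp[i] <- sum(pred & truth == 0L)
    tn[i] <- n0 - fp[i]
    fn[i] <- n1 - tp[i]
  }
  sens <- tp / n1
  spec <- tn / n0
  curve <- data.frame(threshold = thresholds, tp = tp, fp = fp, tn = tn,
                      fn = fn, sensitivity = sens, specificity = spec)
  # thresholds descend along the curve from (1,1) to (0,0); integrate there
  x <- rev(1 - spec); ys <- rev(sens)
  auc <- sum(diff(x) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)

  finite <- is.finite(thresholds)
  cost <- fp + fn
  best <- which(finite & cost == min(cost[finite]))
  best <- best[fp[best] == min(fp[best])]
  optimal <- max(thresholds[best])
  i <- which(thresholds == optimal)[1]
  new("ROCResult", curve = curve, auc = auc, optimalRate = optimal,
      confusion = c(tp = tp[i], fp = fp[i], tn = tn[i], fn = fn[i]))
}

#' Optimal detection rate of an ROC sweep
#'
#' The detection-rate threshold minimizing the number of false positives plus
#' false negatives on the seeds the curve was computed from (ties resolved
#' toward fewer false positives -- discarding a viable seed is cheaper than
#' shipping a nonviable one -- then toward the larger threshold).
#'
#' @param roc an [ROCResult-class].
#' @return the optimal threshold in percent.
#' @export
optimalDetectionRate <- function(roc) {
  stopifnot(is(roc, "ROCResult"))
  roc@optimalRate
}

#' Seed-level classification accuracy by class
#'
#' @param decisions a seed-decision data.frame with `predicted_class` and
#'   `true_class` filled in.
#' @return data.frame with rows `viable`, `nonviable`, `total`: seed counts
#'   and percent correct (`NA` for an empty class).
#' @export
seedAccuracy <- function(decisions) {
  if (any(is.na(decisions$predicted_class)))
    stop("run classifySeeds() first: predicted_class contains NA")
  if (any(is.na(decisions$true_class)))
    stop("true classes are required for accuracy")
  pixelAccuracyFrame <- pixelAccuracy(decisions$predicted_class,
                                      decisions$true_class)
  names(pixelAccuracyFrame)[2] <- "n_seeds"
  pixelAccuracyFrame
}

#' Render the color-coded seed viability map
#'
#' Writes a PNG in which seeds predicted viable are red, seeds predicted
#' nonviable are green, and background is black.
#'
#' @param lmap a [SeedLabelMap-class].
#' @param decisions a classified seed-decision data.frame covering all seeds.
#' @param out destination PNG path.
#' @return the path, invisibly.
#' @export
renderResultMap <- function(lmap, decisions, out) {
  stopifnot(is(lmap, "SeedLabelMap"))
  if (any(is.na(decisions$predicted_class)))
    stop("decisions must be classified (predicted_class present) first")
  k <- nSeeds(lmap)
  if (!all(seq_len(k) %in% decisions$seed_id))
    stop("decisions must cover every seed in the label map")
  lab <- lmap@labels
  cls <- decisions$predicted_class[match(seq_len(k), decisions$seed_id)]
  rgb <- array(0, dim = c(nrow(lab), ncol(lab), 3L))
  red <- lab > 0L & cls[pmax(lab, 1L)] == 1L
  green <- lab > 0L & cls[pmax(lab, 1L)] == 0L
  rgb[, , 1][red] <- 1
  rgb[, , 2][green] <- 1
  png::writePNG(rgb, out)
  invisible(out)
}
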