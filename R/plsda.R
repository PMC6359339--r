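#' Fit a PLS-DA model by NIPALS at a fixed number of latent variables
#'
#' PLS1 regression of the 0/1 class dummy (1 = viable) on mean-centered pixel
#' spectra, by NIPALS with X-side deflation. The factor decomposition is
#' collapsed to coefficients on the raw spectrum scale, so that prediction is
#' `score = sum(x * beta) + b0`; on the training data this equals the factor
#' route to numerical precision. At `nLV = rank(X)` on a full-rank problem the
#' fit coincides with ordinary least squares.
#'
#' @param x a [SpectraTable-class], or a numeric `n x p` matrix.
#' @param y 0/1 integer vector (ignored when `x` is a SpectraTable).
#' @param nLV number of latent variables, `1 <= nLV <= min(p, n - 1)`.
#' @param threshold pixel classification cut (default 0.5).
#' @return a [PLSDAModel-class].
#' @export
fitPLSDA <- function(x, y = NULL, nLV, threshold = 0.5) {
  if (is(x, "SpectraTable")) {
    wl <- x@wavelength; y <- x@y; X <- x@X
  } else {
    X <- x
    wl <- suppressWarnings(as.numeric(colnames(X)))
    if (!length(wl) || any(is.na(wl))) wl <- as.numeric(seq_len(ncol(X)))
  }
  if (!all(is.finite(X))) stop("non-finite values in the spectra matrix")
  y <- as.numeric(y)
  if (length(unique(y)) < 2L)
    stop("degenerate target: both classes must be present in the training set")
  n <- nrow(X); p <- ncol(X)
  nLV <- as.integer(nLV)
  if (nLV < 1L || nLV > min(p, n - 1L))
    stop("nLV must be between 1 and min(n_bands, n_train - 1) = ",
         min(p, n - 1L))
  xMean <- colMeans(X); yMean <- mean(y)
  fac <- nipalsPLS1(sweep(X, 2L, xMean), y - yMean, nLV)
  beta <- betaFromFactors(fac$W, fac$P, fac$q)
  new("PLSDAModel", nLV = ncol(fac$W), W = fac$W, P = fac$P,
      scores = fac$T, q = fac$q, beta = as.numeric(beta),
      b0 = yMean - sum(xMean * beta), xMean = xMean, yMean = yMean,
      rmsecv = numeric(0), wavelength = wl, threshold = threshold)
}

# NIPALS PLS1 (single centered response, X deflation only).
nipalsPLS1 <- function(Xc, yc, A) {
  n <- nrow(Xc); p <- ncol(Xc)
  W <- matrix(0, p, A); P <- matrix(0, p, A); Tm <- matrix(0, n, A)
  q <- numeric(A)
  for (a in seq_len(A)) {
    w <- crossprod(Xc, yc)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      if (a == 1L) stop("X carries no covariance with y; cannot fit")
      warning("covariance exhausted after ", a - 1L,
              " component(s); nLV reduced")
      A <- a - 1L
      W <- W[, seq_len(A), drop = FALSE]; P <- P[, seq_len(A), drop = FALSE]
      Tm <- Tm[, seq_len(A), drop = FALSE]; q <- q[seq_len(A)]
      break
    }
    w <- w / nw
    t <- as.numeric(Xc %*% w)
    tt <- sum(t^2)
    pl <- as.numeric(crossprod(Xc, t)) / tt
    q[a] <- sum(yc * t) / tt
    W[, a] <- w; P[, a] <- pl; Tm[, a] <- t
    Xc <- Xc - tcrossprod(t, pl)
  }
  list(W = W, P = P, T = Tm, q = q)
}

# collapse factors to raw-scale coefficients: beta = W (P'W)^{-1} q
betaFromFactors <- function(W, P, q, A = length(q)) {
  Wa <- W[, seq_len(A), drop = FALSE]
  R <- crossprod(P[, seq_len(A), drop = FALSE], Wa)
  as.numeric(Wa %*% solve(R, q[seq_len(A)]))
}

#' Choose the number of latent variables by cross-validated RMSE
#'
#' Computes RMSECV(A) for A = 1..`maxLV` by grouped cross-validation and
#' refits on the full training set at the A minimizing the curve (first
#' occurrence on ties -- the parsimonious choice where the curve flattens).
#' Folds are formed at the seed level, stratified by class, so no seed's
#' pixels straddle a fold boundary; set `bySeed = FALSE` for plain pixel-level
#' folds.
#'
#' @param train a [SpectraTable-class].
#' @param maxLV largest candidate A; clipped (with a warning) to the
#'   feasible bound.
#' @param nFolds number of CV folds, >= 2 (default 10).
#' @param seed RNG seed controlling fold assignment.
#' @param bySeed group folds by seed (default TRUE).
#' @param threshold pixel classification cut for the returned model.
#' @return a [PLSDAModel-class] with the `rmsecv` slot holding the full curve.
#' @export
selectLatentVariables <- function(train, maxLV, nFolds = 10L, seed = 1L,
                                  bySeed = TRUE, threshold = 0.5) {
  stopifnot(is(train, "SpectraTable"))
  if (nFolds < 2L) stop("nFolds must be >= 2")
  X <- train@X; y <- as.numeric(train@y)
  n <- nrow(X); p <- ncol(X)

  fold <- cvFolds(train, nFolds, seed, bySeed)
  nFolds <- max(fold)
  # feasible bound across folds
  minTrain <- min(vapply(seq_len(nFolds), function(f) sum(fold != f),
                         integer(1)))
  bound <- min(p, minTrain - 1L, n - 1L)
  maxLV <- as.integer(maxLV)
  if (maxLV > bound) {
    warning("maxLV clipped from ", maxLV, " to feasible bound ", bound)
    maxLV <- bound
  }
  if (maxLV < 1L) stop("no feasible latent variable count")

  sqerr <- matrix(NA_real_, n, maxLV)
  for (f in seq_len(nFolds)) {
    hold <- fold == f
    if (!any(hold)) next
    Xtr <- X[!hold, , drop = FALSE]; ytr <- y[!hold]
    if (length(unique(ytr)) < 2L)
      stop("fold ", f, " leaves a single-class training set; reduce nFolds")
    xm <- colMeans(Xtr); ym <- mean(ytr)
    # rank exhaustion at large A is routine inside CV; the achieved count caps a
    fac <- suppressWarnings(nipalsPLS1(sweep(Xtr, 2L, xm), ytr - ym, maxLV))
    Ah <- length(fac$q)
    Xh <- sweep(X[hold, , drop = FALSE], 2L, xm)
    for (a in seq_len(maxLV)) {
      beta <- betaFromFactors(fac$W, fac$P, fac$q, min(a, Ah))
      pred <- ym + as.numeric(Xh %*% beta)
      sqerr[hold, a] <- (y[hold] - pred)^2
    }
  }
  rmsecv <- sqrt(colMeans(sqerr, na.rm = TRUE))
  aStar <- which.min(rmsecv)  # first occurrence on ties
  model <- fitPLSDA(train, nLV = aStar, threshold = threshold)
  model@rmsecv <- rmsecv
  model
}

# fold assignment: round-robin over shuffled seeds (or pixels), per class
cvFolds <- function(train, nFolds, seed, bySeed) {
  y <- train@y
  n <- length(y)
  fold <- integer(n)
  withr::with_seed(seed, {
    if (bySeed) {
      seedClass <- tapply(y, train@seedId, function(v) v[1])
      ids <- as.integer(names(seedClass))
      seedFold <- integer(max(ids))
      for (cl in c(0L, 1L)) {
        clIds <- sample(ids[seedClass == cl])
        seedFold[clIds] <- rep_len(seq_len(nFolds), length(clIds))
      }
      fold <- seedFold[train@seedId]
    } else {
      for (cl in c(0L, 1L)) {
        idx <- sample(which(y == cl))
        fold[idx] <- rep_len(seq_len(nFolds), length(idx))
      }
    }
  })
  fold
}

#' Predict pixel scores and classes from a fitted model
#'
#' `score = x . beta + b0` per spectrum; a pixel is called viable (1) when its
#' score strictly exceeds the model threshold (0.5): a score exactly at the
#' cut is nonviable.
#'
#' @param model a [PLSDAModel-class].
#' @param X numeric `n x p` matrix with `p` matching the model's band count,
#'   or a [SpectraTable-class] (whose axis may be a superset of the model's
#'   bands: the model's wavebands are looked up on it).
#' @return list with `scores` (numeric) and `classes` (integer 0/1).
#' @export
predictPixels <- function(model, X) {
  stopifnot(is(model, "PLSDAModel"))
  if (is(X, "SpectraTable")) {
    idx <- vapply(model@wavelength, function(nm) {
      j <- which(abs(X@wavelength - nm) < 1e-6)
      if (!length(j)) stop("model band ", nm, " nm is not on the table's axis")
      j[1]
    }, integer(1))
    X <- X@X[, idx, drop = FALSE]
  }
  if (ncol(X) != length(model@beta))
    stop("band mismatch: model has ", length(model@beta), " bands, data has ",
         ncol(X))
  scores <- as.numeric(X %*% model@beta) + model@b0
  list(scores = scores, classes = as.integer(scores > model@threshold))
}

#' Pixel-level classification accuracy by class
#'
#' @param classes predicted 0/1 vector.
#' @param truth reference 0/1 vector of equal length.
#' @return data.frame with rows `viable`, `nonviable`, `total`: pixel counts
#'   and percent correct.
#' @export
pixelAccuracy <- function(classes, truth) {
  if (!length(truth) || length(classes) != length(truth))
    stop("classes and truth must be non-empty vectors of equal length")
  acc <- function(keep) {
    if (!any(keep)) return(NA_real_)
    100 * mean(classes[keep] == truth[keep])
  }
  data.frame(
    group = c("viable", "nonviable", "total"),
    n = c(sum(truth == 1), sum(truth == 0), length(truth)),
    accuracy_pct = c(acc(truth == 1), acc(truth == 0), acc(rep(TRUE, length(truth))))
  )
}

#' Variable importance in projection (VIP) scores
#'
#' Wold VIP per band j over the A components:
#' `VIP_j = sqrt( p * sum_a SS_a (w_ja / ||w_a||)^2 / sum_a SS_a )` with
#' `SS_a = q_a^2 * t_a' t_a`, the y-variance explained by component a. The
#' scores satisfy `mean(VIP^2) = 1`; bands scoring above one are informative.
#'
#' @param model a fitted [PLSDAModel-class] (with stored W, scores, q).
#' @return a [VIPResult-class] with an empty selection (see
#'   [selectWavebands()]).
#' @export
vipScores <- function(model) {
  stopifnot(is(model, "PLSDAModel"))
  if (!nrow(model@scores))
    stop("model has no stored training scores; fit with fitPLSDA first")
  W <- model@W
  Wn <- sweep(W, 2L, sqrt(colSums(W^2)), "/")
  ss <- model@q^2 * colSums(model@scores^2)
  p <- nrow(W)
  scores <- sqrt(p * as.numeric(Wn^2 %*% ss) / sum(ss))
  new("VIPResult", scores = scores, wavelength = model@wavelength,
      selected = numeric(0), rule = list())
}

#' Select informative wavebands from a VIP curve
#'
#' Retains the strict local maxima (3-point window) of the VIP curve whose
#' score exceeds `threshold`, plus the two axis endpoints when their score
#' exceeds `threshold` (endpoints cannot be interior peaks but often carry
#' real signal). Peaks closer than `minSeparation` bands to a stronger
#' accepted peak are dropped; `maxBands` optionally caps the selection to the
#' highest-scoring bands.
#'
#' @param vip a [VIPResult-class].
#' @param threshold VIP cut (default 1).
#' @param minSeparation minimum peak separation in bands (default 2).
#' @param maxBands optional cap on the number of selected bands.
#' @return the [VIPResult-class] with `selected` and `rule` filled in; an
#'   empty selection (with a warning) when no score exceeds the threshold.
#' @export
selectWavebands <- function(vip, threshold = 1, minSeparation = 2L,
                            maxBands = NULL) {
  stopifnot(is(vip, "VIPResult"))
  s <- vip@scores; p <- length(s)
  cand <- integer(0)
  if (p >= 1L && s[1] > threshold) cand <- c(cand, 1L)
  if (p >= 3L)
    for (i in 2:(p - 1L))
      if (s[i] > threshold && s[i] > s[i - 1L] && s[i] > s[i + 1L])
        cand <- c(cand, i)
  if (p >= 2L && s[p] > threshold) cand <- c(cand, p)
  # greedy by descending score, enforcing minimum band separation
  cand <- cand[order(-s[cand])]
  keep <- integer(0)
  for (i in cand)
    if (!length(keep) || all(abs(keep - i) >= minSeparation))
      keep <- c(keep, i)
  if (!is.null(maxBands) && length(keep) > maxBands)
    keep <- keep[seq_len(maxBands)]
  if (!length(keep))
    warning("no VIP score above ", threshold, "; empty selection")
  vip@selected <- sort(vip@wavelength[keep])
  vip@rule <- list(threshold = threshold, minSeparation = minSeparation,
                   maxBands = maxBands)
  vip
}

#' Refit a PLS-DA model on a waveband subset
#'
#' Subsets the spectra to the selected wavebands and reruns the
#' cross-validated latent-variable search ([selectLatentVariables()]).
#'
#' @param train a [SpectraTable-class].
#' @param selectedNm wavelengths to keep (nm); each must lie on the table's
#'   axis (within 1e-6 nm).
#' @param maxLV,nFolds,seed,bySeed,threshold passed to
#'   [selectLatentVariables()].
#' @return a [PLSDAModel-class] restricted to the selected bands.
#' @export
refitOnBands <- function(train, selectedNm, maxLV, nFolds = 10L, seed = 1L,
                         bySeed = TRUE, threshold = 0.5) {
  stopifnot(is(train, "SpectraTable"))
  if (!length(selectedNm)) stop("selectedNm must be non-empty")
  idx <- vapply(selectedNm, function(nm) {
    j <- which(abs(train@wavelength - nm) < 1e-6)
    if (!length(j)) stop("band ", nm, " nm is not on the table's axis")
    j[1]
  }, integer(1))
  idx <- sort(unique(idx))
  sub <- new("SpectraTable", X = train@X[, idx, drop = FALSE], y = train@y,
             seedId = train@seedId, wavelength = train@wavelength[idx])
  maxLV <- min(maxLV, length(idx))
  if (maxLV == 1L) {
    m <- fitPLSDA(sub, nLV = 1L, threshold = threshold)
  } else {
    m <- selectLatentVariables(sub, maxLV = maxLV, nFolds = nFolds,
                               seed = seed, bySeed = bySeed,
                               threshold = threshold)
  }
  m
}

#' Save / load a PLSDAModel as JSON
#'
#' Serializes the full model (factors, coefficients, centering constants,
#' RMSECV curve, wavelength axis) to a JSON bundle at full precision.
#'
#' @param model a [PLSDAModel-class].
#' @param path destination path.
#' @return `saveModel`: the path, invisibly; `loadModel`: the restored
#'   [PLSDAModel-class].
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "PLSDAModel"))
  jsonlite::write_json(list(
    nLV = model@nLV, W = model@W, P = model@P, scores = model@scores,
    q = model@q, beta = model@beta, b0 = model@b0, xMean = model@xMean,
    yMean = model@yMean, rmsecv = model@rmsecv,
    wavelength = model@wavelength, threshold = model@threshold
  ), path, digits = NA)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  asMat <- function(m, nr) matrix(as.numeric(m), nrow = nr)
  p <- length(j$beta)
  new("PLSDAModel", nLV = as.integer(j$nLV), W = asMat(j$W, p),
      P = asMat(j$P, p),
      scores = if (length(j$scores)) asMat(j$scores, length(j$scores) / j$nLV)
               else matrix(0, 0, j$nLV),
      q = as.numeric(j$q), beta = as.numeric(j$beta), b0 = as.numeric(j$b0),
      xMean = as.numeric(j$xMean), yMean = as.numeric(j$yMean),
      rmsecv = as.numeric(j$rmsecv), wavelength = as.numeric(j$wavelength),
      threshold = as.numeric(j$threshold))
}

#' Export a VIP curve as CSV
#'
#' Columns: wavelength (nm), VIP score, and whether the band was selected.
#'
#' @param vip a [VIPResult-class].
#' @param path destination CSV path.
#' @return the path, invisibly.
#' @export
exportVIPCSV <- function(vip, path) {
  stopifnot(is(vip, "VIPResult"))
  utils::write.csv(data.frame(
    wavelength_nm = vip@wavelength, vip = vip@scores,
    selected = vip@wavelength %in% vip@selected
  ), path, row.names = FALSE)
  invisible(path)
}
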