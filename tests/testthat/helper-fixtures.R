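# Shared in-code fixtures: tiny cubes, spectra tables and decision frames.

# a tiny deterministic cube with known values
tinyCube <- function(nl = 4, ns = 4, nb = 5, kind = "raw", seed = 1) {
  wl <- seq(1000, 1800, length.out = nb)
  set.seed(seed)
  new("Hypercube", data = array(runif(nl * ns * nb), dim = c(nl, ns, nb)),
      wavelength = wl, kind = kind)
}

# quick small synthetic plate spec
tinyScene <- function(nRows = 2L, nCols = 3L, nb = 40L, rngSeed = 1L, ...) {
  sceneSpec(nRows = nRows, nCols = nCols, seedRadius = 3L, gap = 3L,
            wavelength = seq(1000, 1800, length.out = nb),
            rngSeed = rngSeed, ...)
}

# build a SpectraTable directly: nSeeds per class, pixels per seed, with a
# class mean difference of `sep` on the first band
syntheticTable <- function(nSeedsPerClass = 4, pixelsPerSeed = 10, p = 8,
                           sep = 1, noise = 0.2, seed = 1) {
  set.seed(seed)
  nSeeds <- 2 * nSeedsPerClass
  cls <- rep(c(0L, 1L), each = nSeedsPerClass)
  n <- nSeeds * pixelsPerSeed
  sid <- rep(seq_len(nSeeds), each = pixelsPerSeed)
  y <- cls[sid]
  X <- matrix(rnorm(n * p, sd = noise), n, p)
  X[, 1] <- X[, 1] + sep * y
  new("SpectraTable", X = X, y = y, seedId = sid,
      wavelength = seq(1000, 1800, length.out = p))
}

# seed-decision frame from raw detection percentages
makeDecisions <- function(viableRates, nonviableRates) {
  rates <- c(viableRates, nonviableRates)
  data.frame(seed_id = seq_along(rates), n_total = 100L,
             n_detected = as.integer(rates), detection_pct = rates,
             predicted_class = NA_integer_,
             true_class = rep(c(1L, 0L),
                              c(length(viableRates), length(nonviableRates))))
}

# independent AUC oracle: Mann-Whitney pair counting
aucOracle <- function(rates, truth) {
  r1 <- rates[truth == 1]; r0 <- rates[truth == 0]
  pairs <- outer(r1, r0, function(a, b) (a > b) + 0.5 * (a == b))
  mean(pairs)
}

# independent VIP oracle computed from a model's factors by the formula
vipOracle <- function(model) {
  W <- model@W
  Wn <- sweep(W, 2, sqrt(colSums(W^2)), "/")
  ss <- model@q^2 * colSums(model@scores^2)
  sqrt(nrow(W) * as.numeric(Wn^2 %*% ss) / sum(ss))
}
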