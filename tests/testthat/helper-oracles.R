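# Independent brute-force oracles and small fixtures shared across tests.
# Each oracle is a direct, unoptimized transcription of the defining formula
# so it stays independent of the package's vectorized implementations.

# Maximal sub-threshold runs bordered by above-threshold positions,
# enumerated position by position.
oracleProtectedRuns <- function(y, threshold, minLen = 5L, maxLen = 50L) {
  n <- length(y)
  out <- NULL
  s <- 1L
  while (s <= n) {
    if (y[s] < threshold) {
      e <- s
      while (e < n && y[e + 1L] < threshold) e <- e + 1L
      len <- e - s + 1L
      if (len >= minLen && len <= maxLen && s > 1L && e < n &&
          y[s - 1L] > threshold && y[e + 1L] > threshold)
        out <- rbind(out, c(s, e))
      s <- e + 1L
    } else s <- s + 1L
  }
  if (is.null(out)) matrix(integer(0), ncol = 2) else out
}

# HINT correction evaluated position by position from the printed formula.
oracleHint <- function(y, b) {
  n <- length(y)
  x <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - 25L)
    hi <- min(n, i + 24L)
    yhat <- mean(y[lo:hi])
    bhat <- b[i] / sum(b[lo:hi])
    x[i] <- (y[i] + 1) / (yhat * bhat + 1)
  }
  x
}

# Poisson log-mass from the log-gamma function, independent of dpois.
oracleLogPmf <- function(y, lambda) y * log(lambda) - lambda - lgamma(y + 1)

# Pearson r from the textbook sum formula.
oraclePearson <- function(a, b) {
  am <- a - mean(a)
  bm <- b - mean(b)
  sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
}

# Exact two-sided rank-sum p-value by enumerating all group assignments
# (tie-free inputs, small n).
oracleRankSumP <- function(x, y) {
  r <- rank(c(x, y))
  nx <- length(x)
  wObs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  splits <- combn(length(r), nx)
  w <- apply(splits, 2, function(i) sum(r[i])) - nx * (nx + 1) / 2
  mu <- nx * length(y) / 2
  mean(abs(w - mu) >= abs(wObs - mu) - 1e-9)
}

# Per-position bias values along an interval (shared registration, direct
# lookup).
positionBiasVec <- function(profile, bias, genome) {
  b <- biasValues(bias, hexamerAt(genome, profilePositions(profile)))
  b[is.na(b)] <- 1
  b
}

# Fixture: genome plus a fragment set simulated on a landscape with planted
# fully-protected footprints.
simFixture <- function(len = 5000L, footprints = NULL, depletion = 0,
                       nEvents = 2000L, seed = 42L, bias = NULL) {
  genome <- generateGenome(len, 0.5, seed = seed)
  land <- if (is.null(footprints)) plantLandscape(genome)
  else plantLandscape(genome, footprints, depletion)
  frags <- simulateFragments(genome, land, bias, nEvents = nEvents,
                             seed = seed + 1L)
  list(genome = genome, landscape = land, frags = frags)
}
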