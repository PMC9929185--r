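# Shared fixtures: all synthetic, generated at test time.

# Small, fast stack truth for property-style sweeps (unit tests that do not
# require the full default stack size).
smallStackTruth <- function(...) {
  sceneTruth("stack3d", gridDim = c(64L, 64L, 40L), cellRadius = 2.4, ...)
}

smallTirfTruth <- function(...) {
  sceneTruth("tirf2d", gridDim = c(96L, 96L), cellRadius = 3, ...)
}

# Independent two-pass Pearson implementation (explicit loops; the oracle
# for the package's correlation path).
naivePearson <- function(x, y) {
  n <- length(x)
  mx <- 0; my <- 0
  for (i in seq_len(n)) {
    mx <- mx + x[i] / n
    my <- my + y[i] / n
  }
  sxy <- 0; sxx <- 0; syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  sxy / sqrt(sxx * syy)
}

# Brute-force box mean with symmetric (edge-inclusive) reflect padding.
naiveBoxMean3D <- function(a, r) {
  d <- dim(a)
  reflect <- function(i, n) {
    if (i < 1) 1 - i else if (i > n) 2 * n + 1 - i else i
  }
  out <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    s <- 0
    for (di in -r[1]:r[1]) for (dj in -r[2]:r[2]) for (dk in -r[3]:r[3]) {
      s <- s + a[reflect(i + di, d[1]), reflect(j + dj, d[2]),
                 reflect(k + dk, d[3])]
    }
    out[i, j, k] <- s / prod(2 * r + 1)
  }
  out
}

diceCoef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

riValue <- function(m, region, channel) {
  ri <- m@relativeIntensities
  ri$relativeIntensity[ri$region == region & ri$channel == channel]
}
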